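# shared fixtures: tiny species models and reactions with closed-form truth

oneSite <- function(pka = 5, label = "A") speciesModel(label, pka)

coupledPair <- function(pka = 5, w = log(10), label = "P")
  speciesModel(label, c(pka, pka),
               coupling = matrix(c(0, w, w, 0), 2))

# binding toy: M (pKa 4) + L (no sites) -> ML (pKa 6);
# ddG(pH) = -RT [ln(1+10^(6-pH)) - ln(1+10^(4-pH))] relative to ph_ref
toyBinding <- function() {
  list(models = list(M = speciesModel("M", 4), ML = speciesModel("ML", 6),
                     L = speciesModel("L", numeric(0))),
       reaction = reactionSpec("bind", c(ML = 1), c(M = 1, L = 1),
                               data.frame(product_site = "site1",
                                          ref_species = "M",
                                          ref_site = "site1",
                                          stringsAsFactors = FALSE)))
}

toyBindingExact <- function(ph, ph_ref = 3, temperature = 300) {
  RT <- thermalRT(temperature)
  f <- function(p) -RT * (log(1 + 10^(6 - p)) - log(1 + 10^(4 - p)))
  f(ph) - f(ph_ref)
}

# an alternating 0/1 single-site trace
makeTrace <- function(states, species = "A", ph = 5, replicate = 1L,
                      sids = paste0("site", seq_len(ncol(states)))) {
  new("OccupancyTrace", species = species, ph = ph,
      replicate = as.integer(replicate), seed = 0L, recordInterval = 1L,
      states = matrix(as.integer(states), nrow(states), ncol(states),
                      dimnames = list(NULL, sids)),
      siteIds = sids)
}
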