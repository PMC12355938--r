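# Fixtures built in code: tiny populations and forced phase samples whose
# inclusion probabilities are set by hand, so estimator formulas can be
# checked against hand arithmetic.

# A phase sample with prescribed units and conditional probabilities
# (bypasses the samplers; used to pin estimator formulas to hand values).
force_sample <- function(parent, selected, cond_pi, design_kind = "srs",
                         design_info = NULL) {
  if (is.null(design_info)) {
    M <- length(tprs:::.parent_ids(parent))
    design_info <- switch(design_kind,
      srs = list(n = length(selected), M = M),
      poisson = list(pi = cond_pi, ids = selected),
      stop("provide design_info")
    )
  }
  tprs:::new_phase_sample(selected, cond_pi, parent, design_kind, design_info)
}

# Census phase-I sample (every unit, probability one).
census_phase1 <- function(pop) draw_srs(pop, pop$N)

# Small deterministic population for hand calculations.
toy_pop <- function() finite_population(x = c(1, 2, 3, 5), y = c(2, 4, 1, 3))
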