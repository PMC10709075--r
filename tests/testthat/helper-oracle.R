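# Independent brute-force oracle: straight-line arithmetic sharing no code
# with the package. Counts use trunc(x + 0.5), which is round-half-up for
# the non-negative counts the model produces.

oracle_totals <- function(n_resected, frac, m_hvc, c_hvc, m_lvc, c_lvc,
                          cost_hvc, cost_lvc, round_counts = TRUE) {
  r <- if (round_counts) function(x) trunc(x + 0.5) else function(x) x
  n_h <- r(n_resected * frac)
  n_l <- n_resected - n_h
  comp_h <- r(n_h * c_hvc)
  comp_l <- r(n_l * c_lvc)
  list(
    surgeries = n_h + n_l,
    deaths = r(n_h * m_hvc) + r(n_l * m_lvc),
    complications = comp_h + comp_l,
    cost = comp_h * cost_hvc + comp_l * cost_lvc
  )
}

# Model parameters pinned to an exact resected-cohort size.
params_for_cohort <- function(n_resected, m_hvc = 0.018, c_hvc = 0.343,
                              m_lvc = 0.052, c_lvc = 0.398,
                              cost_hvc = 16815, cost_lvc = 16815,
                              p_hvc = 0.466) {
  model_parameters(
    annual_incidence = n_resected, p_resectable = 1, p_resection = 1,
    p_hvc = p_hvc,
    hvc_rates = center_rates(m_hvc, c_hvc),
    lvc_rates = center_rates(m_lvc, c_lvc),
    cost_per_complication_hvc = cost_hvc,
    cost_per_complication_lvc = cost_lvc
  )
}
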