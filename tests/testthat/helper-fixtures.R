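# Shared fixtures: a one-pool parameter set with Chinese-like storage
# turnover (fast enough for quick simulation-based tests).
fix_one_ev_params <- function() {
  kinetic_params(L_2_1 = 1.5, L_3_2 = 6, DT_3 = 0.1, L_5_4 = 3,
                 L_6_5 = 2, L_5_6 = 2 / (219 / 3.43) - 2.21 / 564,
                 L_10_6 = 5.13 / 219)
}

# identical noise-free synthetic subjects sharing one curve and covariates
fix_identical_subjects <- function(n = 3, params = template_params("CHINESE_LIKE")) {
  spec <- model_spec("TWO_EV")
  curve <- simulate_fdp(params, spec)
  lapply(seq_len(n), function(i) {
    subject_record(id = paste0("ID", i), sex = "F", age = 55,
                   body_weight = 68, bmi = 25, mean_serum_retinol = 1.2,
                   liver_weight = 1339, tracer = curve, group = "SYN")
  })
}
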