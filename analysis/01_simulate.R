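# Stage 1: simulate a two-wave questionnaire study with known ground
# truth. Seven constructs (PHQ, GAD, SR, BD, RP, NAB, NAT); the wave-1
# conditional-independence structure and the wave-1 -> wave-2 transition
# are planted, item responses are Likert-discretized, and a small share
# of records carries quality-control violations.

source("analysis/00_config.R")

truth <- make_default_truth(ana$seed)
print(truth)
P <- truth_partial_cor(truth)
cat("strongest planted partial correlation:",
    max(P[upper.tri(P)]), "(SR-BD)\n")
cat("planted cross-lags:",
    paste(apply(which(truth$B != 0 & diag(7) == 0, arr.ind = TRUE), 1,
                function(ij) paste0(truth$labels[ij[1]], "->",
                                    truth$labels[ij[2]])),
          collapse = ", "), "\n")

sim <- simulate_two_wave_study(truth, n_t1 = ana$n_t1, n_t2 = ana$n_t2,
                               seed = ana$seed)
write.csv(sim$records_t1, ana_path("records_t1.csv"), row.names = FALSE)
write.csv(sim$records_t2, ana_path("records_t2.csv"), row.names = FALSE)

inj1 <- attr(sim$records_t1, "qc_injections")
cat("simulated", nrow(sim$records_t1), "wave-1 and",
    nrow(sim$records_t2), "wave-2 records;",
    nrow(inj1), "wave-1 records carry injected violations\n")
cat("wrote", ana_path("records_t1.csv"), "and records_t2.csv\n")
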