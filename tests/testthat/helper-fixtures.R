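# shared fixtures: built in code, cheap to construct
default_truth <- retention_truth()
default_design <- ccd_design(hilic_factors(), n_center = 6)
default_terms <- expand_terms(default_design)

# noiseless screening study (deterministic)
noiseless_study <- generate_study(default_truth, default_design,
                                  noise = FALSE)

# log10 k response matrix: exactly inside the quadratic model class
noiseless_logk <- log10(as.matrix(
  noiseless_study[c("k_M", "k_A", "k_B", "k_C", "k_D")]))
colnames(noiseless_logk) <- c("moxonidine", "impA", "impB", "impC", "impD")

# least-squares oracle: closed-form normal-equations fit with intercept
ls_oracle <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  qr.coef(qr(X), y)
}

# simulator outcome at given actual conditions
outcome_at <- function(acn, ph, buffer, ...) {
  simulate_retention(default_truth,
                     method_conditions(acn = acn, ph = ph, buffer = buffer),
                     ...)
}
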