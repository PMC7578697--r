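# Small in-code fixtures shared across test files.

# A quick 16-channel feature table with a planted mean shift on `signal`
# channels, built directly (no haemodynamic simulation) for classifier
# and search tests.
quick_feature_table <- function(n_cl = 30, n_hc = 25, shift = 1,
                                signal = integer(0), seed = 42,
                                cits = c("CIT1", "CIT2")) {
  withr::with_seed(seed, {
    n <- (n_cl + n_hc) * length(cits)
    group <- rep(rep(c("CL", "HC"), c(n_cl, n_hc)), length(cits))
    x <- matrix(rnorm(n * 16), n, 16)
    for (ch in signal) x[group == "CL", ch] <- x[group == "CL", ch] + shift
    tab <- tibble::tibble(
      subject_id = rep(c(sprintf("CL%02d", seq_len(n_cl)),
                         sprintf("HC%02d", seq_len(n_hc))), length(cits)),
      group = group,
      cit = rep(cits, each = n_cl + n_hc))
    tab[paste0("ch", 1:16)] <- as.data.frame(x)
    tab
  })
}

# flat hb_series with given constant value, for preprocessing edge cases
constant_hb_series <- function(value = 0, n = 560, dt = 0.65,
                               subject_id = "S1") {
  hb_series(subject_id, matrix(value, n, 16), matrix(value, n, 16),
            dt = dt)
}
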