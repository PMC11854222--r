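# batch-1 conditions constructed in code, independent of the packaged JSON
make_batch1 <- function(...) {
  args <- list(W_s = 0.025, V_s = 0.00024, V_ads0 = 1e-8, V_h = 3.82,
               V_b0 = 40, k_v = 0.00335, n_s0 = 1.6e-7,
               H_Lf = 1.3e-4, beta_sl = 2889.625, beta_ll = 1.01277)
  repl <- list(...)
  args[names(repl)] <- repl
  do.call(batch_config, args)
}

# simple state helper for rhs-level tests
make_state <- function(V_ads, V_b, n_s, n_ads, n_b) {
  list(V_ads = V_ads, V_b = V_b, n_s = n_s, n_ads = n_ads, n_b = n_b)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("%s within %g relative of %s",
                              deparse(substitute(actual)), tol,
                              deparse(substitute(expected))))
}
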