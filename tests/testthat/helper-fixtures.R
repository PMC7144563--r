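# shared fixture builders: everything is generated in code at test time

# raw random descriptor matrix + response with names
rand_xy <- function(seed, n = 10L, p = 5L, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%02d", seq_len(n)),
                              paste0("d", seq_len(p))))
  beta <- if (signal) rnorm(p) else rep(0, p)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = if (signal) 0.1 else 1)
  names(y) <- rownames(X)
  list(X = X, y = y)
}

# autoscaled problem ready for fit_pls
scaled_problem <- function(seed, n = 10L, p = 5L, signal = TRUE) {
  d <- rand_xy(seed, n, p, signal)
  tab <- descriptor_table(d$X)
  resp <- response_block(d$y, name = "y", check_nonneg = FALSE)
  c(autoscale(tab, resp), list(table = tab, response = resp))
}

# small dataset written to a temp CSV, returned with its path
write_tmp_dataset <- function(seed = 1L, n = 6L, p = 3L) {
  d <- rand_xy(seed, n, p)
  tab <- descriptor_table(d$X)
  resp <- response_block(abs(d$y), name = "P_app")
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write_dataset(tab, resp, path)
  list(table = tab, response = resp, path = path)
}
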