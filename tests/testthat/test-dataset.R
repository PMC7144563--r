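test_that("write/read round trip preserves ids, names and values", {
  fx <- write_tmp_dataset(seed = 3, n = 5, p = 4)
  back <- read_dataset(fx$path, "P_app")
  expect_identical(rownames(back$table$values), rownames(fx$table$values))
  expect_identical(colnames(back$table$values), colnames(fx$table$values))
  expect_equal(back$table$values, fx$table$values, tolerance = 1e-12)
  expect_equal(back$response$values, fx$response$values, tolerance = 1e-12)
  expect_identical(back$response$name, "P_app")
})

test_that("read_dataset rejects malformed input with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,d1,d2,P_app", "a,1,2,0.1", "a,3,4,0.2",
               "b,5,6,0.3"), path)
  expect_error(read_dataset(path, "P_app"), "duplicate.*a")

  writeLines(c("compound,d1,d2,P_app", "a,1,2,0.1", "b,oops,4,0.2"), path)
  expect_error(read_dataset(path, "P_app"), "oops.*'b'.*'d1'")

  writeLines(c("compound,d1,d2,d3", "a,1,2,3", "b,4,5,6"), path)
  expect_error(read_dataset(path, "P_app"), "response column")
})

test_that("tab-separated files are auto-detected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\td1\td2\tP_app", "a\t1\t2\t0.1", "b\t3\t4\t0.2",
               "c\t5\t6\t0.3"), path)
  back <- read_dataset(path, "P_app")
  expect_equal(dim(back$table), c(3L, 2L))
  expect_equal(unname(back$response$values), c(0.1, 0.2, 0.3))
})

test_that("a full-size synthetic table survives the CSV round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  spec <- synthetic_spec(seed = 1)
  write_synthetic_qspr(spec, path)
  back <- read_dataset(path, "P_app")
  expect_equal(ncol(back$table$values), 47L)
  expect_equal(nrow(back$table$values), 32L)
  g <- generate_qspr(spec)
  expect_equal(back$table$values, g$table$values, tolerance = 1e-12)
  expect_identical(colnames(back$table$values),
                   descriptor_catalogue()$descriptor)
})

test_that("autoscale centers and scales exactly, with sample sd", {
  tab <- descriptor_table(cbind(a = c(1, 2, 3), b = c(2, 4, 9)),
                          ids = c("x", "y", "z"))
  resp <- response_block(c(1, 5, 6), ids = c("x", "y", "z"), name = "P")
  sc <- autoscale(tab, resp)
  expect_equal(unname(sc$X[, "a"]), c(-1, 0, 1))
  expect_equal(unname(sc$scaling_x$mean["a"]), 2)
  expect_equal(unname(sc$scaling_x$sd["a"]), 1)
  expect_lt(max(abs(colMeans(sc$X))), 1e-10)
  expect_lt(max(abs(apply(sc$X, 2, sd) - 1)), 1e-10)
  expect_lt(abs(mean(sc$y)), 1e-10)
})

test_that("zero-variance descriptors are dropped and recorded", {
  tab <- descriptor_table(cbind(a = c(1, 2, 3), const = c(5, 5, 5)),
                          ids = c("x", "y", "z"))
  resp <- response_block(c(1, 5, 6), ids = c("x", "y", "z"))
  expect_warning(sc <- autoscale(tab, resp), "const")
  expect_identical(sc$scaling_x$excluded_zero_variance, "const")
  expect_identical(colnames(sc$X), "a")
})

test_that("zero-variance response is a hard error", {
  tab <- descriptor_table(cbind(a = c(1, 2, 3)), ids = c("x", "y", "z"))
  resp <- response_block(c(2, 2, 2), ids = c("x", "y", "z"))
  expect_error(autoscale(tab, resp), "zero-variance response")
})

test_that("scaling inverts to the identity on retained columns", {
  sp <- scaled_problem(11, n = 10, p = 5)
  back <- invert_scaling(sp$scaling_x, sp$X)
  expect_lt(max(abs(back - sp$table$values)), 1e-10)
  ys_back <- invert_scaling(sp$scaling_y, sp$y)
  expect_lt(max(abs(ys_back - sp$response$values)), 1e-10)
  # and survives JSON serialization
  js <- scaling_to_json(sp$scaling_x)
  sm2 <- scaling_from_json(js)
  expect_equal(sm2$mean, sp$scaling_x$mean)
  expect_equal(sm2$sd, sp$scaling_x$sd)
})

test_that("exclude_observations drops rows consistently and copies", {
  g <- generate_qspr(synthetic_spec(n_obs = 33, seed = 5))
  out <- exclude_observations(g$table, g$response, "COMP 7")
  expect_equal(nrow(out$table$values), 32L)
  expect_false("COMP 7" %in% names(out$response$values))
  expect_equal(nrow(g$table$values), 33L)  # input untouched

  out0 <- exclude_observations(g$table, g$response, character())
  expect_equal(out0$table$values, g$table$values)

  out3 <- exclude_observations(out$table, out$response,
                               c("COMP 1", "COMP 2", "COMP 3"))
  expect_equal(nrow(out3$table$values), 29L)
  expect_identical(rownames(out3$table$values),
                   names(out3$response$values))

  expect_error(exclude_observations(g$table, g$response, "nope"),
               "unknown observation")
})

test_that("excluding then autoscaling equals autoscaling the subset", {
  g <- generate_qspr(synthetic_spec(seed = 8))
  drop <- c("COMP 4", "COMP 30")
  a <- exclude_observations(g$table, g$response, drop)
  sc_a <- autoscale(a$table, a$response)
  keep <- setdiff(rownames(g$table$values), drop)
  tab_b <- descriptor_table(g$table$values[keep, ])
  resp_b <- response_block(g$response$values[keep], name = "P_app",
                           check_nonneg = FALSE)
  sc_b <- autoscale(tab_b, resp_b)
  expect_equal(sc_a$X, sc_b$X)
  expect_equal(sc_a$y, sc_b$y)
})

test_that("descriptor_table validates its invariants", {
  expect_error(descriptor_table(cbind(a = 1:3), ids = c("x", "x", "y")),
               "duplicate")
  expect_error(descriptor_table(matrix(1:4, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("d", "d")))),
               "duplicate")
  expect_error(descriptor_table(matrix(c(1, Inf, 3, 4), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("u", "v")))),
               "non-finite")
  expect_error(descriptor_table(matrix(1, 1, 1,
                                       dimnames = list("a", "u"))),
               "at least 2")
  expect_error(response_block(c(-1, 2), ids = c("a", "b")), "non-negative")
})
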