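test_that("dense Poisson generation is seeded and rate-faithful", {
  a <- gen_dense(5, 1e-3, 20, seed = 7)
  b <- gen_dense(5, 1e-3, 20, seed = 7)
  expect_identical(a$s_i, b$s_i)
  expect_identical(a$s_j, b$s_j)
  expect_false(identical(a$s_i, gen_dense(5, 1e-3, 20, seed = 8)$s_i))
  # binomial mean 100, sd ~ 9.9: observed counts within 3 sigma
  expect_lt(abs(sum(a$s_i) - 100), 30)
  expect_lt(abs(sum(a$s_j) - 100), 30)
  expect_identical(sum(gen_dense(1, 1e-3, 0, seed = 1)$s_i), 0)
  expect_true(all(gen_dense(0.1, 1e-3, 1000, seed = 1)$s_i == 1))
  expect_error(gen_dense(1, 1e-3, 2000, seed = 1), "rate")
})

test_that("burst scenarios honor their window contracts", {
  ov <- gen_overlap(3, bursts = list(c(0.5, 1.5)), seed = 2)
  mask <- ov$s_i | ov$s_j
  expect_true(all(which(mask) >= 500 & which(mask) <= 1501))
  sp <- gen_separated(4, bursts_i = list(c(0, 1)), bursts_j = list(c(2, 3)),
                      seed = 2)
  expect_identical(sum(sp$s_i * sp$s_j), 0)   # no coincident spikes at all
  expect_error(gen_separated(4, bursts_i = list(c(0, 1)),
                             bursts_j = list(c(0.5, 1.5)), seed = 2),
               "overlap")
  # no bursts -> silence
  expect_identical(sum(gen_overlap(1, bursts = list(), seed = 1)$s_i), 0)
})

test_that("comparison metrics behave like norms and correlations should", {
  s <- gen_dense(1, 1e-3, 20, seed = 3)
  ref <- run_reference(s$s_i, s$s_j, bp)
  rep_df <- compare_traces(ref, ref)
  expect_true(all(rep_df$mean_error == 0 & rep_df$max_error == 0 &
                    rep_df$rmse == 0))
  expect_true(all(rep_df$pearson_r == 1))
  # constant shift: errors see it, correlation does not
  shifted <- ref
  for (cn in trace_cols <- c("z_i", "z_j", "p_i", "p_j", "p_ij",
                             "w_ij", "beta_j"))
    shifted[[cn]] <- ref[[cn]] + 0.5
  rep_df <- compare_traces(ref, shifted)
  expect_true(all(abs(rep_df$rmse - 0.5) < 1e-12))
  expect_true(all(abs(rep_df$pearson_r - 1) < 1e-12))
  expect_true(all(rep_df$mean_error <= rep_df$max_error))
  expect_error(compare_traces(ref, ref[1:10, ]), "length")
})

test_that("constant series get the documented correlation convention", {
  z <- run_reference(rep(0, 50), rep(0, 50), bp)
  expect_true(all(compare_traces(z, z)$pearson_r == 1))
  z2 <- z
  z2$z_i <- z$z_i + 0.1
  expect_warning(rep_df <- compare_traces(z, z2), "undefined")
  expect_true(is.nan(rep_df$pearson_r[rep_df$trace == "z_i"]))
})

test_that("reports round-trip through JSON and tabulate correctly", {
  s <- gen_dense(0.5, 1e-3, 20, seed = 4)
  rep_df <- compare_traces(run_reference(s$s_i, s$s_j, bp),
                           run_emulation(s$s_i, s$s_j, dp, bp))
  expect_identical(nrow(rep_df), 7L)
  tmp <- tempfile(fileext = ".json")
  write_report(rep_df, tmp, "json")
  back <- read_report(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rep_df), tolerance = 1e-12)
  md <- tempfile(fileext = ".md")
  write_report(rep_df, md, "markdown")
  lines <- readLines(md)
  expect_identical(length(lines), 9L)          # header + rule + 7 trace rows
  expect_true(all(grepl("^\\|", lines)))
  expect_error(write_report(rep_df[0, ], tempfile(), "json"), "populated")
})

test_that("spike and trace CSVs round-trip", {
  s <- gen_dense(0.2, 1e-3, 50, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_spike_csv(s, f)
  back <- read_spike_csv(f)
  expect_identical(back$s_i, s$s_i)
  expect_identical(back$s_j, s$s_j)
  ref <- run_reference(s$s_i, s$s_j, bp)
  f2 <- tempfile(fileext = ".csv")
  write_trace_csv(ref, f2)
  back2 <- read_trace_csv(f2)
  expect_equal(back2$w_ij, ref$w_ij, tolerance = 1e-12)
})

test_that("config files map onto parameter constructors", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("bcpnn:", "  kp: 0.004", "  eps: 0.02",
               "device:", "  k_off: 30", "readout:", "  i_read: 4.0e-8",
               "hcu:", "  n_pre: 6", "  n_post: 6"), cfg)
  got <- read_config(cfg)
  expect_equal(got$bcpnn$kp, 0.004)
  expect_equal(got$bcpnn$kz_i, 1 / 11)         # untouched default
  expect_equal(got$device$k_off, 30)
  expect_equal(got$chain$i_read, 4e-8)
  expect_equal(got$hcu$n_pre, 6)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("device:", "  r_onn: 12"), bad)
  expect_error(read_config(bad), "unknown keys")
})
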