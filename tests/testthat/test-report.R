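test_that("reproduce_figure validates its inputs and writes traceable outputs", {
  expect_error(reproduce_figure("fig9"), "arg")
  out_dir <- withr::local_tempdir()
  fig <- reproduce_figure("fig3", out_dir = out_dir,
                          quad = quad_spec(rel_tol = 1e-6))
  expect_named(fig, c("data", "plots"))
  expect_s3_class(fig$plots$contours, "ggplot")
  expect_true(all(fig$data$contours$p_det < 0.6))
  expect_true(file.exists(file.path(out_dir, "fig3_contours.csv")))
  manifest <- jsonlite::read_json(file.path(out_dir, "fig3_manifest.json"))
  expect_equal(manifest$command, "reproduce_figure")
  expect_true(all(vapply(manifest$outputs, file.exists, logical(1))))
})

test_that("detection-vs-size curve data reproduce the headline bounds", {
  fig <- reproduce_figure("fig2", quad = quad_spec(rel_tol = 1e-6))
  curves <- fig$data$curves
  expect_equal(sort(unique(curves$regime)), c("fast", "moderate", "slow"))
  expect_lt(max(curves$p_det), 0.6)
  expect_s3_class(fig$plots$curves, "ggplot")
  # density panels: frequency bias flips from 0 toward 1 with tumor size
  dens <- fig$data$density
  small <- dens[dens$size == "small", ]
  large <- dens[dens$size == "large", ]
  expect_gt(small$density[small$alpha == 0.01],
            small$density[small$alpha == 0.99])
  expect_lt(large$density[large$alpha == 0.01],
            large$density[large$alpha == 0.99])
})

test_that("two-driver curve tables carry both drivers and their sum", {
  fig <- reproduce_figure("s3", quad = quad_spec(rel_tol = 1e-6))
  sweep <- fig$data$curves
  expect_true(all(c("P1", "P2", "total") %in% names(sweep)))
  expect_equal(sweep$total, sweep$P1 + sweep$P2)
  expect_true(all(sweep$total >= 0 & sweep$total <= 1))
})

test_that("manifests record command, parameters, seed and outputs", {
  path <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(path, "scan-grid", list(n_points = 12), seed = 1,
                     outputs = "scan.csv")
  m <- jsonlite::read_json(path)
  expect_equal(m$command, "scan-grid")
  expect_equal(m$params$n_points, 12)
  expect_equal(m$seed, 1)
  expect_equal(m$package, "subdriver")
})

test_that("the command-line wrapper computes and documents a detection run", {
  cli <- system.file("cli", "subdriver.R", package = "subdriver")
  expect_true(file.exists(cli))
  out <- withr::local_tempfile(fileext = ".csv")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "detect-prob", "--g", "0.7", "--M", "1e8",
                   "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  tab <- utils::read.csv(out)
  p <- branching_params(b = 0.14, r = 0.01, g = 0.7, u = 1e-5, M = 1e8)
  expect_equal(tab$p_det, detection_probability(p), tolerance = 1e-7)
  manifest <- paste0(tools::file_path_sans_ext(out), "_manifest.json")
  expect_true(file.exists(manifest))
})
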