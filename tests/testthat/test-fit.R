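sim_small <- generate_planted_dataset(plant_spec(m = 10, peak_len = 100,
                                                 seed = 14))

test_that("the fitting function returns a ranked classed model set", {
  fit <- suppressMessages(exomotif(sim_small$peaks))
  expect_s3_class(fit, "exomotif")
  expect_gt(length(fit$motifs), 0)
  expect_s3_class(fit$motifs[[1]], "motif_model")
  scores <- vapply(fit$motifs, function(m) sum(m$instances$score), 0)
  expect_true(all(diff(scores) <= 1e-9))
  expect_equal(fit$motifs[[1]]$name, "motif_1")
  expect_equal(fit$mode, "cov")
})

test_that("print, summary, coef, plot and predict methods work", {
  fit <- suppressMessages(exomotif(sim_small$peaks))
  expect_output(print(fit), "motif_1")
  s <- summary(fit)
  expect_s3_class(s, "summary.exomotif")
  expect_output(print(s), "width")
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(dim(cf[[1]]), c(4L, fit$motifs[[1]]$width))
  pdf(NULL)
  expect_silent(plot(fit, motifs = 1))
  dev.off()
  pr <- predict(fit)
  expect_length(pr, length(sim_small$peaks))
  # planted peaks outscore fresh background sequences
  set.seed(15)
  bg <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  }, "")
  expect_gt(mean(pr[sim_small$truth$seq]), mean(predict(fit, bg)))
})

test_that("basic mode drops coverage and FASTA input auto-selects it", {
  fit <- suppressMessages(exomotif(sim_small$peaks, mode = "basic"))
  expect_equal(fit$mode, "basic")
  f <- withr::local_tempfile(fileext = ".fa")
  write_peak_fasta(sim_small$peaks, f)
  fit2 <- suppressMessages(exomotif(f))
  expect_equal(fit2$mode, "basic")
  expect_error(exomotif(f, mode = "cov"), "no coverage")
  expect_error(suppressWarnings(exomotif("no/such/file.fa")), "cannot interpret")
})

test_that("coverage-FASTA input auto-selects coverage mode", {
  f <- withr::local_tempfile(fileext = ".cfa")
  write_covfasta(sim_small$peaks, f)
  fit <- suppressMessages(exomotif(f))
  expect_equal(fit$mode, "cov")
})

test_that("fits are deterministic: identical MEME output byte for byte", {
  f1 <- withr::local_tempfile(fileext = ".meme")
  f2 <- withr::local_tempfile(fileext = ".meme")
  fit1 <- suppressMessages(exomotif(sim_small$peaks))
  fit2 <- suppressMessages(exomotif(sim_small$peaks))
  write_meme(fit1, f1)
  write_meme(fit2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("instance BED output is well-formed and sequence-relative", {
  fit <- suppressMessages(exomotif(sim_small$peaks))
  f <- withr::local_tempfile(fileext = ".bed")
  write_instance_bed(fit, sim_small$peaks, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(ncol(bed), 6)
  expect_true(all(bed$V2 >= 0))
  expect_true(all(bed$V3 <= max(nchar(sim_small$peaks$seq))))
  expect_true(all(bed$V6 %in% c("+", "-")))
  widths <- vapply(fit$motifs, `[[`, 0L, "width")
  names(widths) <- vapply(fit$motifs, `[[`, "", "name")
  expect_equal(bed$V3 - bed$V2, unname(widths[bed$V4]))
})

test_that("the command line wrapper runs discover, simulate and evaluate", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "exomotif.R", package = "exomotif")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- withr::local_tempdir()

  sim_file <- file.path(out, "sim.cfa")
  truth_file <- file.path(out, "truth.bed")
  st <- system2(rscript, c(cli, "simulate", "--m", "8", "--peak-len", "90",
                           "--seed", "5", "--out", sim_file,
                           "--truth", truth_file))
  expect_equal(st, 0L)
  expect_true(file.exists(sim_file) && file.exists(truth_file))
  expect_length(read_covfasta(sim_file), 8)

  st2 <- system2(rscript, c(cli, "discover", "--covfasta", sim_file,
                            "--out", out, "--seed", "5"))
  expect_equal(st2, 0L)
  expect_true(file.exists(file.path(out, "motifs.meme")))
  expect_true(file.exists(file.path(out, "instances.bed")))
  expect_true(file.exists(file.path(out, "config.txt")))

  st3 <- system2(rscript, c(cli, "evaluate", "--motifs",
                            file.path(out, "motifs.meme"),
                            "--positives", sim_file, "--seed", "5",
                            "--out", file.path(out, "pauc.tsv")))
  expect_equal(st3, 0L)
  tab <- read.delim(file.path(out, "pauc.tsv"))
  expect_true(all(c("motif", "pauc_sensitivity", "pauc_specificity") %in%
                    names(tab)))

  # missing input exits nonzero
  st4 <- system2(rscript, c(cli, "discover", "--fasta", "absent.fa",
                            "--out", out), stderr = NULL)
  expect_gt(st4, 0L)
})
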