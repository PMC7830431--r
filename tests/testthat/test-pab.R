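test_that("homology profiles distinguish X-derived from random sequence", {
  withr::local_seed(61)
  x <- tibble::tibble(id = "X", sequence = rand_seq(40000))
  par_contig <- mutate_at_rate(substr(x$sequence, 5001, 25000), 0.99)
  prof <- homology_profile(par_contig, x, window = 2000, step = 1000)
  expect_equal(nrow(prof),
               ceiling((nchar(par_contig) - 2000) / 1000) + 1)
  expect_true(all(prof$covered_fraction > 0.95))
  expect_true(all(abs(prof$mean_identity - 0.99) < 0.01))

  rnd <- rand_seq(20000)
  prof0 <- homology_profile(rnd, x, window = 2000, step = 1000)
  expect_true(all(prof0$covered_fraction < 0.05))

  short <- rand_seq(1500)
  expect_equal(nrow(homology_profile(short, x, window = 2000, step = 1000)),
               1L)
  expect_error(homology_profile(rnd, x, window = 500), "window")
  expect_error(homology_profile(rnd, x, window = 2000, step = 3000), "step")
})

test_that("the fixture boundary contig shows one high-to-low transition", {
  prof <- paper_pab()$profile
  cov <- prof$covered_fraction
  high <- cov > 0.5
  expect_true(high[1])
  expect_false(high[length(high)])
  expect_equal(sum(diff(high) != 0), 1L) # single transition
})

test_that("the planted boundary is recovered to base-level precision", {
  call <- paper_pab()$call
  expect_equal(nrow(call), 1L)
  expect_lt(abs(call$boundary - 177307L), 1000L)
  expect_gte(call$par_side_identity, 0.95)
})

test_that("uniformly homologous contigs yield no boundary call", {
  withr::local_seed(62)
  x <- tibble::tibble(id = "X", sequence = rand_seq(60000))
  par_contig <- mutate_at_rate(substr(x$sequence, 1, 50000), 0.99)
  prof <- homology_profile(par_contig, x, window = 2000, step = 1000)
  expect_equal(nrow(detect_boundary(prof, par_contig, x)), 0L)
  rnd_prof <- homology_profile(rand_seq(50000), x, window = 2000,
                               step = 1000)
  expect_equal(nrow(detect_boundary(rnd_prof)), 0L)
})

test_that("randomly planted breakpoints are recovered within one step", {
  withr::local_seed(63)
  x <- tibble::tibble(id = "X", sequence = rand_seq(60000))
  window <- 2000L
  step <- 500L
  for (i in 1:8) {
    bp <- sample(15000:35000, 1)
    contig <- paste0(mutate_at_rate(substr(x$sequence, 1, bp), 0.99),
                     rand_seq(50000 - bp))
    prof <- homology_profile(contig, x, window = window, step = step)
    call <- detect_boundary(prof, contig, x, min_flank_windows = 3L)
    expect_equal(nrow(call), 1L)
    expect_lte(abs(call$boundary - bp), step)
  }
})

test_that("boundary refinement is stable under window/step halving", {
  fx <- paper_fixture()
  xref <- dplyr::filter(fx$female_reference, scaffold_class == "X")
  bd <- dplyr::filter(fx$y_contigs, id == "tig419")
  coarse <- paper_pab()$call
  prof <- homology_profile(bd, xref, window = 5000L, step = 1000L)
  fine <- detect_boundary(prof, bd, xref)
  expect_lte(abs(fine$boundary - coarse$boundary), 1000L)
})

test_that("gametolog divergence recovers planted identity", {
  withr::local_seed(64)
  x <- rand_seq(1500)
  expect_equal(gametolog_divergence(x, x)$identity, 1)
  fx <- paper_fixture()
  gp <- fx$gametolog_pair
  gd <- gametolog_divergence(gp$x_copy, gp$y_copy)
  expect_lt(abs(gd$identity - 0.984), 0.005)
  rnd <- gametolog_divergence(rand_seq(1000), rand_seq(1000))
  expect_false(rnd$homologous)
  expect_error(gametolog_divergence(rand_seq(100), rand_seq(1000)), "200")
})

test_that("PAR contigs order along the template and flip with strand", {
  fx <- paper_fixture()
  xref <- dplyr::filter(fx$female_reference, scaffold_class == "X")
  par_rows <- dplyr::filter(fx$truth, feature == "PAR_CONTIG")
  parc <- dplyr::filter(fx$y_contigs, id %in% par_rows$contig_id)
  placed <- order_par_contigs(parc, xref)
  expect_true(all(placed$status == "PLACED"))
  truth_order <- par_rows$contig_id[order(par_rows$source_start)]
  expect_equal(placed$contig_id, truth_order)
  # placements do not overlap after ordering
  expect_true(all(placed$t_start[-1] >= placed$t_end[-nrow(placed)]))

  rc1 <- dplyr::mutate(parc[1, ], sequence = ytriage:::revcomp(sequence))
  placed_rc <- order_par_contigs(dplyr::bind_rows(rc1, parc[-1, ]), xref)
  expect_equal(placed_rc$t_start[placed_rc$contig_id == parc$id[1]],
               placed$t_start[placed$contig_id == parc$id[1]])
  expect_equal(placed_rc$orientation[placed_rc$contig_id == parc$id[1]],
               "inverted")

  stray <- tibble::tibble(id = "stray", sequence = rand_seq(5000),
                          length = 5000L)
  placed2 <- order_par_contigs(dplyr::bind_rows(parc, stray), xref)
  expect_equal(placed2$status[placed2$contig_id == "stray"], "UNPLACED")
})

test_that("PAR coverage reporting exposes both rounding conventions", {
  pub <- alpaca_assembly_summary()
  pc <- par_coverage(pub[["par_bases"]], pub[["estimated_par_bases"]])
  expect_equal(pc$percent, 53.4)
  expect_true(pc$percent_integer %in% c(53L, 54L))
  expect_equal(par_coverage(54, 100)$percent_integer, 54L)
})
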