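test_that("background subtraction floors at zero and records its estimate", {
  const <- image_stack(array(1, c(5, 8, 8)), array(100, c(5, 8, 8)))
  region <- array(TRUE, c(5, 8, 8))
  out <- subtract_background(const, region)
  expect_true(all(out$channels$foci == 0))
  expect_equal(out$meta$background_estimate, 100)
  # zero background is the identity
  id <- subtract_background(const, 0)
  expect_identical(id$channels$foci, const$channels$foci)
  expect_error(subtract_background(const, array(FALSE, c(5, 8, 8))),
               class = "g4quant_error")
  expect_error(subtract_background(const, -1), class = "g4quant_error")
})

test_that("subtracting the planted background restores blob amplitude", {
  cfg <- noise_free_config(seed = 9, nuclear_sizes = 20L, cyto_foci_mean = 0)
  sim <- simulate_cell_stack(cfg)
  sub <- subtract_background(sim$stack, !sim$truth$cell_mask)
  expect_equal(sub$meta$background_estimate, cfg$background_mean)
  vox <- sim$truth$foci$voxels[[1]]
  lin <- vox[, 1] + (vox[, 2] - 1) * 5 + (vox[, 3] - 1) * 5 * 64
  # blob intensity profile: amplitude at the centre, floored at 60% of it
  inside <- sub$channels$foci[lin]
  expect_true(all(inside >= 0.6 * cfg$focus_amplitude - 1e-9))
  expect_true(all(inside <= cfg$focus_amplitude + 1e-9))
  expect_gt(max(inside), 0.8 * cfg$focus_amplitude)
  # outside the blob (and away from nucleoli) the subtracted channel is 0
  rest <- sub$channels$foci
  rest[lin] <- NA
  rest[sim$truth$nucleolus_mask] <- NA
  expect_true(all(abs(rest) < 1e-9, na.rm = TRUE))
})

test_that("clearing outside the ROI zeroes exactly the complement", {
  cfg <- sim_config(seed = 10)
  sim <- simulate_cell_stack(cfg)
  whole <- cell_roi(array(TRUE, dim(sim$roi$mask)), "all")
  expect_identical(clear_outside_roi(sim$stack, whole)$channels,
                   sim$stack$channels)
  masked <- clear_outside_roi(sim$stack, sim$roi)
  expect_true(all(masked$channels$foci[!sim$roi$mask] == 0))
  expect_true(all(masked$channels$dapi[!sim$roi$mask] == 0))
  expect_identical(masked$channels$foci[sim$roi$mask],
                   sim$stack$channels$foci[sim$roi$mask])
  expect_error(cell_roi(array(FALSE, c(5, 8, 8))), class = "g4quant_error")
})

test_that("nucleus segmentation recovers the planted ellipsoid", {
  cfg <- sim_config(seed = 12)
  sim <- simulate_cell_stack(cfg)
  masked <- clear_outside_roi(sim$stack, sim$roi)
  nuc <- segment_nucleus(masked, sim$roi)
  jaccard <- sum(nuc & sim$truth$nucleus_mask) /
    sum(nuc | sim$truth$nucleus_mask)
  expect_gte(jaccard, 0.95)
})

test_that("nucleus segmentation rejects constant DAPI and keeps the largest blob", {
  flat <- image_stack(array(5, c(5, 10, 10)), array(0, c(5, 10, 10)))
  roi <- cell_roi(array(TRUE, c(5, 10, 10)))
  expect_error(segment_nucleus(flat, roi), class = "g4quant_error")

  dapi <- array(1, c(5, 12, 12))
  dapi[2:4, 2:6, 2:6] <- 100   # larger blob
  dapi[2:3, 9:11, 9:11] <- 100 # smaller blob
  two <- image_stack(dapi, array(0, c(5, 12, 12)))
  nuc <- segment_nucleus(two, cell_roi(array(TRUE, c(5, 12, 12))),
                         fill_holes = FALSE)
  expect_true(all(nuc[2:4, 2:6, 2:6]))
  expect_false(any(nuc[, 9:11, 9:11]))
})

test_that("foci segmentation thresholds and labels with frozen parameters", {
  arr <- array(0, c(5, 10, 10))
  arr[3, 5, 5] <- 10                       # isolated voxel
  arr[1, 1, 1] <- 10; arr[2, 2, 2] <- 10   # corner-touching pair
  st <- image_stack(array(1, c(5, 10, 10)), arr)
  p26 <- foci_params(background_mean = 0, background_sd = 1, k = 3)
  lab <- segment_foci(st, p26)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab == lab[3, 5, 5]), 1L)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2]) # one component at 26-connectivity
  p6 <- foci_params(background_mean = 0, background_sd = 1, k = 3,
                    connectivity = 6)
  lab6 <- segment_foci(st, p6)
  expect_false(lab6[1, 1, 1] == lab6[2, 2, 2])
})

test_that("the frozen-parameters rule is enforced across experiments", {
  st <- image_stack(array(1, c(5, 6, 6)), array(0, c(5, 6, 6)))
  p <- foci_params(background_mean = 0, background_sd = 1,
                   experiment_id = "exp1")
  expect_silent(segment_foci(st, p, experiment_id = "exp1"))
  expect_error(segment_foci(st, p, experiment_id = "exp2"),
               class = "g4quant_frozen_params_error")
  expect_silent(segment_foci(st, p, experiment_id = "exp2", override = TRUE))
  expect_error(foci_params(background_mean = 10, background_sd = 1,
                           threshold = 5),
               class = "g4quant_error")
})

test_that("threshold estimation from NT fields reproduces mean + k * SD", {
  cfgs <- lapply(1:3, function(i) sim_config(seed = 100 + i))
  sims <- lapply(cfgs, simulate_cell_stack)
  p <- estimate_foci_params(lapply(sims, `[[`, "stack"),
                            lapply(sims, function(s) !s$truth$cell_mask),
                            k = 3, experiment_id = "e1")
  expect_equal(p$threshold, p$background_mean + 3 * p$background_sd)
  expect_equal(p$background_mean, 100, tolerance = 0.02)
  expect_equal(p$background_sd, 8, tolerance = 0.05)
})

size_filter_fixture <- function(sizes_nuclear, sizes_cyto = integer()) {
  # hand-built label array: nucleus occupies y <= 20; components are
  # disjoint straight runs of the requested sizes
  dm <- c(5L, 40L, 120L)
  comp <- array(0L, dm)
  nucleus <- array(FALSE, dm)
  nucleus[, 1:20, ] <- TRUE
  lab <- 0L
  place_run <- function(comp, size, ystart) {
    lab <<- lab + 1L
    n_per_row <- min(size, 100L)
    rows <- ceiling(size / n_per_row)
    left <- size
    for (r in seq_len(rows)) {
      take <- min(left, n_per_row)
      comp[3, ystart + (r - 1), seq_len(take) + 2] <- lab
      left <- left - take
    }
    comp
  }
  y <- 1L
  for (s in sizes_nuclear) {
    comp <- place_run(comp, s, y)
    y <- y + 3L
  }
  y <- 22L
  for (s in sizes_cyto) {
    comp <- place_run(comp, s, y)
    y <- y + 3L
  }
  list(comp = comp, nucleus = nucleus)
}

test_that("voxel-size filters cut exactly at the documented boundaries", {
  fx <- size_filter_fixture(c(2L, 3L, 100L, 101L), c(19L, 20L, 100L, 101L))
  out <- classify_and_filter(fx$comp, fx$nucleus, mode = "tasq")
  by_label <- setNames(out$compartment, out$label)
  expect_equal(unname(by_label[as.character(1:4)]),
               c("discarded", "nuclear", "nuclear", "nucleolar"))
  expect_equal(unname(by_label[as.character(5:8)]),
               c("discarded", "cytoplasmic", "cytoplasmic", "discarded"))
  expect_true(all(!is.na(out$reason[out$compartment == "discarded"])))
  # partition: every component lands in exactly one bucket
  expect_equal(sum(table(out$compartment)), nrow(out))
  expect_equal(nrow(out), 8L)
})

test_that("gh2ax mode keeps only nuclear components of at least the minimum size", {
  fx <- size_filter_fixture(c(1L, 2L, 150L), c(30L))
  out <- classify_and_filter(fx$comp, fx$nucleus, mode = "gh2ax")
  by_label <- setNames(out$compartment, out$label)
  expect_equal(unname(by_label[as.character(1:4)]),
               c("discarded", "nuclear", "nuclear", "discarded"))
  out3 <- classify_and_filter(fx$comp, fx$nucleus, mode = "gh2ax",
                              min_gh2ax_voxels = 3L)
  expect_equal(sum(out3$compartment == "nuclear"), 1L)
})

test_that("size filters are monotone in their bounds", {
  withr::with_seed(77, {
    fx <- size_filter_fixture(sample(1:120, 8), sample(1:120, 6))
    counts <- function(minv) {
      out <- classify_and_filter(fx$comp, fx$nucleus, mode = "tasq",
                                 nuclear_size = c(minv, 100L))
      sum(out$compartment == "nuclear")
    }
    cs <- vapply(1:10, counts, integer(1))
    expect_true(all(diff(cs) <= 0))
    wide <- classify_and_filter(fx$comp, fx$nucleus, mode = "tasq",
                                nuclear_size = c(1L, 100L))
    narrow <- classify_and_filter(fx$comp, fx$nucleus, mode = "tasq",
                                  nuclear_size = c(5L, 80L))
    expect_gte(sum(wide$compartment == "nuclear"),
               sum(narrow$compartment == "nuclear"))
  })
})

test_that("quantify_cell recovers planted counts exactly in separable noise-free mode", {
  cfg <- noise_free_config(
    seed = 31,
    nuclear_sizes = c(3L, 7L, 15L, 40L, 70L, 100L, 5L, 9L, 12L, 33L),
    cyto_sizes = c(20L, 45L, 100L, 60L, 21L)
  )
  sim <- simulate_cell_stack(cfg)
  cq <- quantify_cell(sim$stack, sim$roi, exact_params("e"), mode = "tasq",
                      experiment_id = "e")
  expect_equal(cq$summary$n_nuclear, 10L)
  expect_equal(cq$summary$n_cytoplasmic, 5L)
  expect_equal(cq$summary$n_nucleolar,
               max(label_components(sim$truth$nucleolus_mask, 26)))
  # measured voxel counts equal the planted sizes
  kept <- cq$foci[cq$foci$compartment == "nuclear", ]
  expect_equal(sort(kept$voxel_count), sort(cfg$nuclear_sizes))
})

test_that("a background-only cell yields zero counts everywhere", {
  cfg <- noise_free_config(seed = 32, nuclear_foci_mean = 0,
                           cyto_foci_mean = 0, n_nucleoli = c(0L, 0L))
  sim <- simulate_cell_stack(cfg)
  cq <- quantify_cell(sim$stack, sim$roi, exact_params(), mode = "tasq")
  expect_equal(cq$summary$n_components, 0L)
  expect_equal(cq$summary$n_nuclear + cq$summary$n_cytoplasmic +
                 cq$summary$n_nucleolar, 0L)
})

test_that("planted oversize nuclear objects are reported as nucleoli, not foci", {
  cfg <- noise_free_config(seed = 33, n_nucleoli = c(1L, 1L),
                           nucleolus_size_range = c(400L, 400L),
                           nuclear_foci_mean = 0, cyto_foci_mean = 0)
  sim <- simulate_cell_stack(cfg)
  cq <- quantify_cell(sim$stack, sim$roi, exact_params(), mode = "tasq")
  expect_equal(cq$summary$n_nucleolar, 1L)
  expect_equal(cq$summary$n_nuclear, 0L)
  expect_equal(cq$foci$voxel_count[cq$foci$compartment == "nucleolar"], 400L)
  expect_equal(sum(cq$nucleolus_mask), 400L)
})

test_that("gamma-H2AX mode counts nuclear foci per nucleus on 7-plane stacks", {
  cfg <- noise_free_config(seed = 35,
                           dim = c(z = 7L, y = 64L, x = 64L),
                           nucleus_semiaxes = c(z = 3.2, y = 18, x = 18),
                           cell_semiaxes = c(z = 3.6, y = 26, x = 26),
                           n_nucleoli = c(0L, 0L), # no nucleolar staining here
                           nuclear_sizes = c(2L, 3L, 10L, 150L),
                           cyto_sizes = c(25L, 30L))
  sim <- simulate_cell_stack(cfg)
  cq <- quantify_cell(sim$stack, sim$roi, exact_params(), mode = "gh2ax")
  # all nuclear components of >= 2 voxels count, regardless of upper size;
  # cytoplasmic staining is ignored entirely
  expect_equal(cq$summary$n_nuclear, 4L)
  expect_equal(cq$summary$n_cytoplasmic, 0L)
  expect_equal(cq$summary$n_discarded, 2L)
  reasons <- cq$foci$reason[cq$foci$compartment == "discarded"]
  expect_true(all(reasons == "no overlap with the nucleus"))
})

test_that("errors inside quantify_cell carry the ROI id", {
  cfg <- sim_config(seed = 34)
  sim <- simulate_cell_stack(cfg)
  flat <- sim$stack
  flat$channels$dapi <- array(1, dim(flat$channels$dapi))
  err <- tryCatch(
    quantify_cell(flat, sim$roi, exact_params(), mode = "tasq"),
    error = function(e) e
  )
  expect_s3_class(err, "g4quant_cell_error")
  expect_match(conditionMessage(err), sim$roi$roi_id, fixed = TRUE)
})
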