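test_that("composite r2 matches a hand-computed Pearson oracle", {
  tag <- c(0L, 1L, 2L, 2L, 0L)
  partner <- c(0L, 1L, 1L, 2L, 0L)
  calls <- make_calls(cbind(tag = tag, v2 = partner))
  scan <- r2_scan(calls, "tag")
  expect_equal(scan$r_squared[scan$variant_id == "v2"], 45 / 56,
               tolerance = 1e-10)
  expect_equal(scan$r_squared[scan$variant_id == "v2"],
               r2_oracle(tag, partner), tolerance = 1e-10)
  expect_equal(scan$r_squared[scan$variant_id == "tag"], 1)

  orth <- make_calls(cbind(tag = c(0L, 0L, 1L, 1L), v2 = c(0L, 1L, 0L, 1L)))
  s2 <- r2_scan(orth, "tag")
  expect_equal(s2$r_squared[s2$variant_id == "v2"], 0, tolerance = 1e-12)
})

test_that("r2 is symmetric and invariant to allele-coding flips", {
  set.seed(3)
  a <- sample(0:2, 10, replace = TRUE)
  b <- sample(0:2, 10, replace = TRUE)
  calls <- make_calls(cbind(va = a, vb = b))
  r_ab <- r2_scan(calls, "va")
  r_ba <- r2_scan(calls, "vb")
  expect_equal(r_ab$r_squared[r_ab$variant_id == "vb"],
               r_ba$r_squared[r_ba$variant_id == "va"], tolerance = 1e-12)

  flipped <- make_calls(cbind(va = a, vb = 2L - b))
  r_f <- r2_scan(flipped, "va")
  expect_equal(r_f$r_squared[r_f$variant_id == "vb"],
               r_ab$r_squared[r_ab$variant_id == "vb"], tolerance = 1e-12)
})

test_that("monomorphic variants are handled per contract", {
  calls <- make_calls(cbind(tag = c(1L, 1L, 1L), v2 = c(0L, 1L, 2L)))
  expect_error(r2_scan(calls, "tag"), "monomorphic")
  calls2 <- make_calls(cbind(tag = c(0L, 1L, 2L), v2 = c(1L, 1L, 1L)))
  s <- r2_scan(calls2, "tag")
  expect_true(s$excluded[s$variant_id == "v2"])
  expect_true(is.na(s$r_squared[s$variant_id == "v2"]))
  expect_error(r2_scan(calls2, "nope"), "not present")
})

test_that("the scan window restricts partners by distance", {
  calls <- make_calls(cbind(tag = c(0L, 1L, 2L), far = c(0L, 1L, 2L)),
                      pos = c(1e6, 1e6 + 1300 * 1000))
  s <- r2_scan(calls, "tag", window_kb = 1200)
  expect_false("far" %in% s$variant_id)
  s2 <- r2_scan(calls, "tag", window_kb = 1400)
  expect_true("far" %in% s2$variant_id)
})

test_that("divergence calling recovers exactly the planted divergent SNVs", {
  cfg <- clean_config(n_samples = 80, n_divergent_snvs = 50, seed = 13)
  ch <- simulate_cohort(cfg)
  calls <- filter_variants_for_ld(apply_call_filters(ch$calls))
  scan <- r2_scan(calls, cfg$tag_id)
  divergent <- call_divergent_snvs(scan)
  planted <- ch$variants$variant_id[ch$variants$role == "divergent"]
  expect_setequal(divergent, planted)
})

test_that("divergence threshold is inclusive and the tag always returned", {
  stats <- tibble::tibble(
    variant_id = c("a", "tag", "b", "c"),
    chrom = "chr17", pos = c(100, 200, 300, 400),
    r_squared = c(1.0, 1.0, 0.98, 0.995), n_used = 10, excluded = FALSE
  )
  attr(stats, "tag_id") <- "tag"
  expect_setequal(call_divergent_snvs(stats, r2_min = 0.99),
                  c("a", "tag", "c"))
  expect_false("b" %in% call_divergent_snvs(stats))
})

test_that("tag homozygotes match the generating truth labels", {
  cfg <- clean_config(n_samples = 150, seed = 19)
  ch <- simulate_cohort(cfg)
  hom <- find_tag_homozygotes(ch$calls, cfg$tag_id)
  truth <- ch$meta$sample_id[ch$meta$h2_dosage == 2L]
  expect_setequal(hom, truth)

  small <- make_calls(cbind(tag = c(2L, 1L, 0L)))
  expect_identical(find_tag_homozygotes(small, "tag"), "S001")
})

test_that("recombinant segments are maximal runs around the tag", {
  # 10 divergent sites, tag at the 5th; one clean homozygote, one with a
  # proximal recombinant masking the first three sites.
  d <- rbind(clean = rep(2L, 10),
             prox = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
  rownames(d) <- c("clean", "prox")
  colnames(d) <- c(sprintf("d%02d", 1:4), "tag", sprintf("d%02d", 6:10))
  calls <- make_calls(d)
  segs <- detect_recombinant_segments(calls, c("clean", "prox"),
                                      colnames(d), "tag")
  pos <- sort(unique(calls$pos))
  clean_row <- segs[segs$sample_id == "clean", ]
  expect_identical(c(clean_row$start, clean_row$end), c(pos[1], pos[10]))
  expect_identical(clean_row$breakpoint_side, "none")
  prox_row <- segs[segs$sample_id == "prox", ]
  expect_identical(c(prox_row$start, prox_row$end), c(pos[4], pos[10]))
  expect_identical(prox_row$breakpoint_side, "proximal")

  int <- minimal_ld_interval(segs)
  expect_identical(c(int$start, int$end), c(pos[4], pos[10]))
})

test_that("segment detection agrees with a brute-force maximal-run oracle", {
  set.seed(101)
  n_sites <- 20
  ids <- sprintf("s%02d", 1:n_sites)
  tag_idx <- 10
  ids[tag_idx] <- "tag"
  for (rep in 1:20) {
    d <- matrix(2L, 1, n_sites, dimnames = list("H", ids))
    mask <- runif(n_sites) < 0.3
    mask[tag_idx] <- FALSE
    d[1, mask] <- 1L
    calls <- make_calls(d)
    segs <- detect_recombinant_segments(calls, "H", ids, "tag")
    # brute force: widest (i, j) containing the tag with all dosage 2
    best <- c(tag_idx, tag_idx)
    for (i in 1:tag_idx) for (j in tag_idx:n_sites) {
      if (all(d[1, i:j] == 2L) && (j - i) > (best[2] - best[1])) {
        best <- c(i, j)
      }
    }
    pos <- sort(unique(calls$pos))
    expect_identical(c(segs$start, segs$end), c(pos[best[1]], pos[best[2]]))
  }
})

test_that("inconsistent homozygote input is an error", {
  d <- matrix(c(1L, 2L), 1, 2, dimnames = list("X", c("tag", "d2")))
  calls <- make_calls(d)
  expect_error(detect_recombinant_segments(calls, "X", c("tag", "d2"), "tag"),
               "not homozygous")
})

test_that("minimal interval is the intersection and shrinks monotonically", {
  one <- tibble::tibble(sample_id = "a", chrom = "chr17",
                        start = 100, end = 1000, breakpoint_side = "none")
  expect_identical(c(minimal_ld_interval(one)$start,
                     minimal_ld_interval(one)$end), c(100, 1000))

  two <- dplyr::bind_rows(
    one |> dplyr::mutate(start = 200, end = 1000),
    one |> dplyr::mutate(sample_id = "b", start = 100, end = 900))
  int <- minimal_ld_interval(two)
  expect_identical(c(int$start, int$end), c(200, 900))

  set.seed(5)
  segs <- one |> dplyr::mutate(start = 1, end = 10000)
  for (k in 1:10) {
    extra <- tibble::tibble(sample_id = paste0("s", k), chrom = "chr17",
                            start = runif(1, 1, 4000),
                            end = runif(1, 5000, 10000),
                            breakpoint_side = "both")
    prev <- minimal_ld_interval(segs)
    segs <- dplyr::bind_rows(segs, extra)
    cur <- minimal_ld_interval(segs)
    expect_gte(cur$start, prev$start)
    expect_lte(cur$end, prev$end)
  }

  disjoint <- dplyr::bind_rows(
    one |> dplyr::mutate(start = 100, end = 200),
    one |> dplyr::mutate(sample_id = "b", start = 300, end = 400))
  expect_error(minimal_ld_interval(disjoint), "empty intersection")
  expect_error(minimal_ld_interval(one[0, ]), "no segments")
})
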