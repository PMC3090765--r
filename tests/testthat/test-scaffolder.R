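test_that("estimate_gap is the insert minus the two tails", {
  l <- data.frame(insert_mean = c(5000, 4000, 5e6),
                  tail_a = c(100, 2500, 10000),
                  tail_b = c(150, 2000, 20000))
  expect_equal(estimate_gap(l), c(4750, -500, 4970000))
})

mklink <- function(a, ea, ta, b, eb, tb, lib = "pe4k", pri = 1L,
                   mean = 4000, tol = 800, gap = NULL, id = "r") {
  d <- data.frame(library = lib, priority = pri, insert_mean = mean,
                  tolerance = tol, contig_a = a, end_a = ea, tail_a = ta,
                  contig_b = b, end_b = eb, tail_b = tb,
                  read_a = paste0(id, "/1"), read_b = paste0(id, "/2"),
                  stringsAsFactors = FALSE)
  d$gap <- if (is.null(gap)) estimate_gap(d) else gap
  d
}

test_that("bundle_links groups by pair/ends/priority and takes median gaps", {
  links <- rbind(
    mklink("c1", "high", 100, "c2", "low", 200, gap = 4700, id = "x"),
    mklink("c1", "high", 120, "c2", "low", 180, gap = 4750, id = "y"),
    # same physical join fed in swapped order: must canonicalise into it
    mklink("c2", "low", 210, "c1", "high", 90, gap = 4800, id = "z"))
  bd <- bundle_links(links)
  expect_equal(nrow(bd), 1)
  expect_equal(bd$weight, 3L)
  expect_equal(bd$gap, 4750)
  expect_equal(bd$contig_a, "c1")   # canonical pair order

  # a single priority-1 link is below the default weight threshold
  expect_equal(nrow(bundle_links(mklink("c1", "high", 1, "c2", "low", 1))), 0)
  # a single priority-2 (map) link survives
  expect_equal(nrow(bundle_links(
    mklink("c1", "high", 1, "c2", "low", 1, pri = 2L))), 1)

  # opposite end combinations form distinct bundles
  two <- rbind(
    mklink("c1", "high", 1, "c2", "low", 1, pri = 2L),
    mklink("c1", "high", 1, "c2", "high", 1, pri = 2L))
  expect_equal(nrow(bundle_links(two)), 2)
})

test_that("a single bundle joins two contigs at the estimated gap", {
  bd <- bundle_links(rbind(
    mklink("c1", "high", 100, "c2", "low", 150, mean = 5000, id = "a"),
    mklink("c1", "high", 100, "c2", "low", 150, mean = 5000, id = "b")))
  sc <- greedy_scaffold(bd, c(c1 = 2000, c2 = 3000))
  pl <- sc$placements
  expect_equal(nrow(sc$scaffolds), 1)
  expect_equal(pl$contig_id, c("c1", "c2"))
  expect_equal(pl$offset, c(0, 2000 + 4750))
  expect_equal(pl$orientation, c("+", "+"))
  expect_equal(pl$gap_after[1], 4750)
  expect_equal(sc$scaffolds$span, 2000 + 4750 + 3000)
})

# brute-force all orders and orientations of a 3-contig chain and keep the
# layouts satisfying both bundles, via the independent geometry oracle
test_that("a consistent chain recovers the unique consistent layout", {
  lens <- c(A = 1000, B = 2000, C = 1500)
  bundles <- rbind(
    bundle_from_layout("A", 0, "+", 1000, "B", 1200, "-", 2000),
    bundle_from_layout("B", 1200, "-", 2000, "C", 3500, "+", 1500))
  bundles <- canon_bundles(bundles)
  bd <- bundles[order(bundles$contig_a), ]
  bd$weight <- c(3L, 2L)

  satisfies <- function(layout, bun) {
    # layout: data.frame contig, low, orient
    for (k in seq_len(nrow(bun))) {
      pa <- layout[layout$contig == bun$contig_a[k], ]
      pb <- layout[layout$contig == bun$contig_b[k], ]
      sa <- if (pa$orient == "+") 1 else -1
      sb <- if (pb$orient == "+") 1 else -1
      oa <- if (sa > 0) pa$low else pa$low + lens[pa$contig]
      ob <- if (sb > 0) pb$low else pb$low + lens[pb$contig]
      rel <- oracle_rel(bun$end_a[k], bun$end_b[k], bun$gap[k],
                        lens[bun$contig_a[k]], lens[bun$contig_b[k]])
      if (sa * rel[2] != sb) return(FALSE)
      if (abs(oa + sa * rel[1] - ob) > bun$tolerance[k]) return(FALSE)
    }
    TRUE
  }
  got <- greedy_scaffold(bd, lens)
  expect_equal(nrow(got$scaffolds), 1)
  expect_equal(nrow(got$conflicts), 0)
  lay <- data.frame(contig = got$placements$contig_id,
                    low = got$placements$offset,
                    orient = got$placements$orientation,
                    stringsAsFactors = FALSE)
  expect_true(satisfies(lay, bd))
  # and the greedy layout matches the truth it was derived from (up to
  # global flip): A+, B-, C+ at lows 0/1200/3500
  truth <- data.frame(contig = c("A", "B", "C"), low = c(0, 1200, 3500),
                      orient = c("+", "-", "+"), stringsAsFactors = FALSE)
  same <- all(lay[match(truth$contig, lay$contig), "orient"] == truth$orient)
  span <- max(truth$low + lens[truth$contig])
  flipped <- data.frame(contig = truth$contig,
                        low = span - (truth$low + lens[truth$contig]),
                        orient = ifelse(truth$orient == "+", "-", "+"))
  expect_true(satisfies(truth, bd) &&
              (same || all(lay[match(flipped$contig, lay$contig), "orient"]
                           == flipped$orient)))
})

test_that("when two bundles contradict, the better-sorted one wins", {
  lens <- c(A = 1000, B = 1000)
  # same orientation (high-low => parallel) with weight 5 vs
  # opposite orientation (high-high => antiparallel) with weight 2
  bd <- data.frame(
    contig_a = "A", end_a = "high", contig_b = "B",
    end_b = c("low", "high"), priority = 1L, weight = c(5L, 2L),
    gap = 100, tolerance = 1000, stringsAsFactors = FALSE)
  got <- greedy_scaffold(bd, lens)
  expect_equal(nrow(got$conflicts), 1)
  expect_equal(got$conflicts$weight, 2L)
  expect_equal(got$conflicts$reason, "orientation")
  expect_equal(got$placements$orientation, c("+", "+"))
})

test_that("sequence bundles override contradicting map bundles at any weight", {
  lens <- c(A = 1000, B = 1000)
  for (w_map in c(1L, 10L, 100L)) {
    bd <- data.frame(
      contig_a = "A", end_a = "high", contig_b = "B",
      end_b = c("low", "high"),
      priority = c(1L, 2L), weight = c(2L, w_map),
      gap = 100, tolerance = c(1000, 1e6), stringsAsFactors = FALSE)
    got <- greedy_scaffold(bd, lens)
    expect_equal(got$conflicts$priority, 2L)
    expect_equal(got$placements$orientation, c("+", "+"),
                 info = paste("map weight", w_map))
  }
})

test_that("every contig lands in exactly one scaffold, runs are reproducible", {
  set.seed(3)
  lens <- setNames(round(runif(12, 1000, 9000)), sprintf("t%02d", 1:12))
  links <- do.call(rbind, lapply(1:30, function(i) {
    ab <- sample(names(lens), 2)
    mklink(ab[1], sample(c("low", "high"), 1), round(runif(1, 0, 500)),
           ab[2], sample(c("low", "high"), 1), round(runif(1, 0, 500)),
           pri = sample(1:2, 1), id = paste0("r", i))
  }))
  bd <- bundle_links(links, min_weight = c("1" = 1, "2" = 1))
  s1 <- greedy_scaffold(bd, lens)
  s2 <- greedy_scaffold(bd, lens)
  expect_identical(s1, s2)
  expect_setequal(s1$placements$contig_id, names(lens))
  expect_equal(anyDuplicated(s1$placements$contig_id), 0L)
  # byte-identical AGP across runs
  f1 <- tempfile(); f2 <- tempfile()
  write_agp(s1, f1); write_agp(s2, f2)
  expect_identical(readLines(paste0(f1, ".agp")),
                   readLines(paste0(f2, ".agp")))
})

test_that("conflict-free instances of up to 6 contigs are fully satisfied", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    ids <- sprintf("k%d", seq_len(n))
    lens <- setNames(round(runif(n, 1000, 8000)), ids)
    orient <- sample(c("+", "-"), n, replace = TRUE)
    gaps <- round(runif(n - 1, -200, 3000))
    low <- cumsum(c(0, lens[-n] + gaps))
    # bundles from every true adjacency, plus some skip-level constraints
    bun <- do.call(rbind, lapply(seq_len(n - 1), function(i)
      bundle_from_layout(ids[i], low[i], orient[i], lens[i],
                         ids[i + 1], low[i + 1], orient[i + 1], lens[i + 1],
                         weight = sample(2:6, 1))))
    if (n > 2) {
      i <- sample(n - 2, 1)
      bun <- rbind(bun,
        bundle_from_layout(ids[i], low[i], orient[i], lens[i],
                           ids[i + 2], low[i + 2], orient[i + 2],
                           lens[i + 2], priority = 2L))
    }
    bun <- canon_bundles(bun)
    got <- greedy_scaffold(bun, lens)
    expect_equal(nrow(got$conflicts), 0, info = paste("rep", rep))
    expect_equal(nrow(got$scaffolds), 1)
    # exhaustive agreement: greedy satisfies every bundle of a
    # conflict-free instance (the achievable maximum)
    expect_true(all(check_bundles_against_layout(bun, got)),
                info = paste("rep", rep))
  }
})

test_that("accepted bundles stay consistent with the final layout", {
  set.seed(23)
  lens <- setNames(round(runif(10, 2000, 9000)), sprintf("m%02d", 1:10))
  orient <- sample(c("+", "-"), 10, replace = TRUE)
  gaps <- round(runif(9, 0, 2000))
  low <- cumsum(c(0, lens[-10] + gaps))
  bun <- canon_bundles(do.call(rbind, lapply(1:9, function(i)
    bundle_from_layout(names(lens)[i], low[i], orient[i], lens[i],
                       names(lens)[i + 1], low[i + 1], orient[i + 1],
                       lens[i + 1]))))
  # one deliberately contradicting map bundle (flipped orientation)
  bad <- bun[5, ]; bad$end_b <- if (bad$end_b == "low") "high" else "low"
  bad$priority <- 2L
  got <- greedy_scaffold(rbind(bun, bad), lens)
  expect_equal(nrow(got$conflicts), 1)
  accepted <- bun
  expect_true(all(check_bundles_against_layout(accepted, got)))
})

test_that("AGP round-trips through read_agp and FASTA renders gaps", {
  bd <- bundle_links(rbind(
    mklink("c1", "high", 100, "c2", "low", 150, mean = 5000, id = "a"),
    mklink("c1", "high", 100, "c2", "low", 150, mean = 5000, id = "b")))
  lens <- c(c1 = 200, c2 = 300)
  # with short contigs the 4750 gap stands out in sequence
  sc <- greedy_scaffold(bd, lens)
  pre <- tempfile()
  write_agp(sc, pre)
  back <- read_agp(paste0(pre, ".agp"))
  expect_equal(back$placements$contig_id, sc$placements$contig_id)
  expect_equal(back$placements$offset, sc$placements$offset)
  expect_equal(back$scaffolds$span, sc$scaffolds$span)

  ctgs <- Biostrings::DNAStringSet(c(c1 = strrep("A", 200),
                                     c2 = strrep("C", 300)))
  fa <- tempfile(fileext = ".fa")
  write_scaffold_fasta(sc, ctgs, fa)
  seq <- as.character(Biostrings::readDNAStringSet(fa)[[1]])
  expect_equal(nchar(seq), 200 + 4750 + 300)
  expect_equal(substr(seq, 201, 201), "N")
})
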