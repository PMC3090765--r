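#' Configuration for the synthetic fixture generator
#'
#' The defaults describe a small but realistically structured world: one
#' 10 Mb chromosome fragmented into log-normal contigs (mean 30 kb, sd
#' 15 kb) separated by sequencing gaps of 0.5-3.5 kb; a marker map at
#' 5 markers/Mb whose positions carry uniform +/-2 Mb noise (FISH-scale
#' imprecision, which is why pseudo mate-pair intervals start at 5 Mb);
#' and two FR paired-end libraries (4 kb and 8 kb nominal inserts, 100 bp
#' reads, 1.5x coverage each) mirroring the mate-pair library sizes used
#' for low-coverage marsupial assemblies.
#'
#' @param seed Mandatory RNG seed; every random choice derives from it.
#' @param n_chromosomes,chr_len Number of chromosomes and their length (bp).
#' @param contig_mean,contig_sd Log-normal contig length moments (bp).
#' @param gap_min,gap_max Uniform inter-contig gap bounds (bp).
#' @param marker_density Markers per Mb (Poisson).
#' @param marker_len Marker footprint on the genome (bp).
#' @param marker_noise Uniform half-width of map position noise (bp).
#' @param libraries List of paired-end library definitions, each a list
#'   with `name`, `insert_mean`, `insert_sd`, `read_len`, `coverage`.
#' @param duplicate_segment If TRUE, ~20 read pairs are flagged MAPQ 0 on
#'   both mates, emulating reads from a repeated segment, to exercise the
#'   multi-mapper filter.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 1L, chr_len = 10e6,
                       contig_mean = 30e3, contig_sd = 15e3,
                       gap_min = 500, gap_max = 3500,
                       marker_density = 5, marker_len = 1000,
                       marker_noise = 2e6,
                       libraries = list(
                         list(name = "pe4k", insert_mean = 4000,
                              insert_sd = 200, read_len = 100, coverage = 1.5),
                         list(name = "pe8k", insert_mean = 8000,
                              insert_sd = 400, read_len = 100, coverage = 1.5)),
                       duplicate_segment = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(chr_len > 0, contig_mean > 0, gap_min >= 0, gap_max >= gap_min,
            marker_len > 0, marker_noise >= 0, marker_density >= 0)
  if (contig_mean >= chr_len)
    stop("contig mean length must be below the chromosome length")
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chr_len = chr_len, contig_mean = contig_mean,
                 contig_sd = contig_sd, gap_min = gap_min, gap_max = gap_max,
                 marker_density = marker_density, marker_len = marker_len,
                 marker_noise = marker_noise, libraries = libraries,
                 duplicate_segment = duplicate_segment),
            class = "sim_config")
}

#' Generate a complete synthetic scaffolding fixture
#'
#' Writes, under `out_dir`: `contigs.fa` (random A/C/G/T contig sequences),
#' `map.tsv` (virtual marker map with noisy positions), `markers.psl`
#' (each placed marker's exact alignment to its contig, score = marker
#' length), one headered SAM per read library (`lib_<name>.sam`, FR pairs,
#' `NM:i:0`), `libraries.tsv` (library definitions for downstream
#' parsing), `truth.agp` plus `truth_contigs.tsv` / `truth_adjacencies.tsv`
#' (the ground-truth layout). Contigs tile each chromosome left to right
#' with uniform gaps; each contig is stored in a random orientation so the
#' scaffolder has real orientation work to do. Markers whose footprint
#' falls inside a gap stay on the map but get no placement, like map genes
#' missing from a fragmented assembly. Read pairs are drawn uniformly from
#' the chromosome with Gaussian insert sizes; a mate overlapping a gap is
#' unsequenceable and the pair is not emitted.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `truth` tables, the file paths and
#'   the config.
#' @export
simulate_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + (config$contig_sd / config$contig_mean)^2))
  meanlog <- log(config$contig_mean) - sdlog^2 / 2

  contigs <- list(); adjacencies <- list(); ctg_n <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    pos <- 0; rows <- list()
    repeat {
      clen <- max(1000, round(stats::rlnorm(1, meanlog, sdlog)))
      if (pos + clen > config$chr_len) {
        clen <- config$chr_len - pos
        if (clen < 1000) break
      }
      ctg_n <- ctg_n + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = sprintf("ctg%05d", ctg_n), chrom = chrom,
        start = pos, length = clen,
        orientation = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      gap <- round(stats::runif(1, config$gap_min, config$gap_max))
      pos <- pos + clen + gap
      if (pos >= config$chr_len) break
    }
    chr_ctg <- do.call(rbind, rows)
    contigs[[ci]] <- chr_ctg
    if (nrow(chr_ctg) > 1) {
      a <- chr_ctg[-nrow(chr_ctg), ]; b <- chr_ctg[-1, ]
      adjacencies[[ci]] <- data.frame(
        contig_a = a$contig_id, orient_a = a$orientation,
        contig_b = b$contig_id, orient_b = b$orientation,
        gap = b$start - (a$start + a$length), chrom = chrom,
        stringsAsFactors = FALSE)
    }
  }
  contigs <- do.call(rbind, contigs)
  adjacencies <- if (length(adjacencies) > 0) do.call(rbind, adjacencies) else
    data.frame(contig_a = character(), orient_a = character(),
               contig_b = character(), orient_b = character(),
               gap = numeric(), chrom = character(), stringsAsFactors = FALSE)
  rownames(contigs) <- rownames(adjacencies) <- NULL

  # contig sequences: content is irrelevant to the pipeline, length is not
  seqs <- vapply(contigs$length, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- contigs$contig_id
  fa_path <- file.path(out_dir, "contigs.fa")
  Biostrings::writeXStringSet(dna, fa_path, width = 80L)

  # markers: Poisson count per chromosome, uniform true positions
  mk_rows <- list(); psl_rows <- list(); mk_n <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    cc <- contigs[contigs$chrom == chrom, ]
    n_mk <- stats::rpois(1, config$marker_density * config$chr_len / 1e6)
    if (n_mk == 0) next
    tp <- sort(round(stats::runif(n_mk, 0, config$chr_len - config$marker_len)))
    ids <- sprintf("MK%05d", mk_n + seq_len(n_mk)); mk_n <- mk_n + n_mk
    noise <- round(stats::runif(n_mk, -config$marker_noise, config$marker_noise))
    map_pos <- pmax(0, pmin(config$chr_len - 1, tp + noise))
    mk_rows[[ci]] <- data.frame(
      marker_id = ids, chromosome = chrom, map_pos = map_pos,
      gene_name = paste0("GENE_", ids),
      source = sample(c("FISH", "linkage", "synteny"), n_mk, replace = TRUE,
                      prob = c(0.05, 0.35, 0.60)),
      stringsAsFactors = FALSE)
    # placement: marker footprint fully inside one contig
    idx <- findInterval(tp, cc$start)
    ok <- idx >= 1 & (tp + config$marker_len) <= (cc$start[idx] + cc$length[idx])
    if (!any(ok)) next
    i <- idx[ok]
    fwd <- cc$orientation[i] == "+"
    t_start <- ifelse(fwd, tp[ok] - cc$start[i],
                      cc$start[i] + cc$length[i] - (tp[ok] + config$marker_len))
    psl_rows[[ci]] <- data.frame(
      matches = config$marker_len, misMatches = 0L, repMatches = 0L,
      nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L, tNumInsert = 0L,
      tBaseInsert = 0L, strand = ifelse(fwd, "+", "-"),
      qName = ids[ok], qSize = config$marker_len, qStart = 0L,
      qEnd = config$marker_len, tName = cc$contig_id[i],
      tSize = cc$length[i], tStart = t_start,
      tEnd = t_start + config$marker_len, blockCount = 1L,
      blockSizes = paste0(config$marker_len, ","), qStarts = "0,",
      tStarts = paste0(t_start, ","), stringsAsFactors = FALSE)
  }
  map_tab <- if (length(mk_rows) > 0) do.call(rbind, mk_rows) else
    data.frame(marker_id = character(), chromosome = character(),
               map_pos = numeric(), gene_name = character(),
               source = character(), stringsAsFactors = FALSE)
  map_path <- file.path(out_dir, "map.tsv")
  data.table::fwrite(map_tab, map_path, sep = "\t", quote = FALSE)
  psl_path <- file.path(out_dir, "markers.psl")
  psl_tab <- if (length(psl_rows) > 0) do.call(rbind, psl_rows) else NULL
  if (is.null(psl_tab)) writeLines(character(0), psl_path) else
    data.table::fwrite(psl_tab, psl_path, sep = "\t", quote = FALSE,
                       col.names = FALSE)

  # paired-end reads, one SAM per library
  sq_lines <- sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id,
                      as.integer(contigs$length))
  sam_paths <- character(0)
  for (lib in config$libraries) {
    rec <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- paste0("chr", ci)
      cc <- contigs[contigs$chrom == chrom, ]
      L <- lib$read_len
      n_pairs <- round(lib$coverage * config$chr_len / (2 * L))
      ins <- pmax(2 * L + 1, round(stats::rnorm(n_pairs, lib$insert_mean,
                                                lib$insert_sd)))
      s <- floor(stats::runif(n_pairs) * (config$chr_len - ins))
      g1s <- s; g1e <- s + L              # forward mate, genome coords
      g2s <- s + ins - L; g2e <- s + ins  # reverse mate
      locate <- function(gs, ge) {
        i <- findInterval(gs, cc$start)
        ok <- i >= 1 & ge <= (cc$start[pmax(i, 1)] + cc$length[pmax(i, 1)])
        list(i = i, ok = ok)
      }
      l1 <- locate(g1s, g1e); l2 <- locate(g2s, g2e)
      keep <- l1$ok & l2$ok
      if (!any(keep)) next
      i1 <- l1$i[keep]; i2 <- l2$i[keep]
      to_contig <- function(i, gs, ge, fwd_read) {
        plus <- cc$orientation[i] == "+"
        list(contig = cc$contig_id[i],
             pos0 = ifelse(plus, gs - cc$start[i],
                           cc$start[i] + cc$length[i] - ge),
             rev = ifelse(plus, !fwd_read, fwd_read))
      }
      m1 <- to_contig(i1, g1s[keep], g1e[keep], TRUE)
      m2 <- to_contig(i2, g2s[keep], g2e[keep], FALSE)
      qn <- sprintf("%s_%s_p%07d", lib$name, chrom, seq_len(sum(keep)))
      mapq <- rep(60L, sum(keep))
      if (isTRUE(config$duplicate_segment)) {
        n_dup <- min(20L, length(mapq))
        mapq[sample.int(length(mapq), n_dup)] <- 0L
      }
      flag1 <- 0x1L + 0x40L + ifelse(m1$rev, 0x10L, 0L) +
        ifelse(m2$rev, 0x20L, 0L)
      flag2 <- 0x1L + 0x80L + ifelse(m2$rev, 0x10L, 0L) +
        ifelse(m1$rev, 0x20L, 0L)
      fmt <- function(q, flag, m, other)
        sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*\tNM:i:0",
                q, flag, m$contig, m$pos0 + 1L, mapq, L,
                ifelse(other$contig == m$contig, "=", other$contig),
                other$pos0 + 1L)
      rec[[length(rec) + 1L]] <- as.vector(rbind(fmt(qn, flag1, m1, m2),
                                                 fmt(qn, flag2, m2, m1)))
    }
    sam_path <- file.path(out_dir, paste0("lib_", lib$name, ".sam"))
    writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq_lines, unlist(rec)), sam_path)
    sam_paths <- c(sam_paths, sam_path)
  }
  lib_tab <- do.call(rbind, lapply(config$libraries, function(l)
    data.frame(name = l$name, insert_mean = l$insert_mean,
               insert_sd = l$insert_sd, read_len = l$read_len,
               coverage = l$coverage, stringsAsFactors = FALSE)))
  data.table::fwrite(lib_tab, file.path(out_dir, "libraries.tsv"),
                     sep = "\t", quote = FALSE)

  truth <- list(contigs = contigs, adjacencies = adjacencies)
  data.table::fwrite(contigs, file.path(out_dir, "truth_contigs.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(adjacencies, file.path(out_dir, "truth_adjacencies.tsv"),
                     sep = "\t", quote = FALSE)
  .write_truth_agp(truth, file.path(out_dir, "truth.agp"))
  invisible(list(truth = truth, config = config,
                 paths = list(contigs = fa_path, map = map_path,
                              psl = psl_path, sam = sam_paths,
                              dir = out_dir)))
}

.write_truth_agp <- function(truth, path) {
  lines <- "##agp-version\t2.0"
  for (chrom in unique(truth$contigs$chrom)) {
    cc <- truth$contigs[truth$contigs$chrom == chrom, ]
    part <- 0L
    for (i in seq_len(nrow(cc))) {
      if (i > 1) {
        gs <- cc$start[i - 1] + cc$length[i - 1]
        part <- part + 1L
        lines <- c(lines, paste(chrom, gs + 1, cc$start[i], part, "N",
                                cc$start[i] - gs, "scaffold", "yes",
                                "paired-ends", sep = "\t"))
      }
      part <- part + 1L
      lines <- c(lines, paste(chrom, cc$start[i] + 1,
                              cc$start[i] + cc$length[i], part, "W",
                              cc$contig_id[i], 1, cc$length[i],
                              cc$orientation[i], sep = "\t"))
    }
  }
  writeLines(lines, path)
}

#' Read a fixture's truth tables back from disk
#'
#' @param dir Fixture directory written by [simulate_fixture()].
#' @return `list(contigs=, adjacencies=)`.
#' @export
read_truth <- function(dir) {
  list(contigs = as.data.frame(data.table::fread(
         file.path(dir, "truth_contigs.tsv"))),
       adjacencies = as.data.frame(data.table::fread(
         file.path(dir, "truth_adjacencies.tsv"))))
}

.flip <- function(o) ifelse(o == "+", "-", "+")

# canonical key for an oriented adjacency: an adjacency read right-to-left
# with both orientations flipped is the same physical join
.adj_key <- function(a, oa, b, ob) {
  k1 <- paste(a, oa, b, ob)
  k2 <- paste(b, .flip(ob), a, .flip(oa))
  pmin(k1, k2)
}

# unordered contig-pair key, orientation ignored
.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

#' Score a scaffold layout against the simulated truth
#'
#' Compares the oriented adjacency sets: precision is the fraction of
#' predicted consecutive contig pairs that are true neighbours with the
#' correct relative orientation; recall the fraction of true adjacencies
#' recovered. Orientation errors count predicted adjacencies that join the
#' right contig pair but flip one contig relative to the other.
#'
#' @param scaffold_set Result of [greedy_scaffold()].
#' @param truth Truth list from [simulate_fixture()] or [read_truth()].
#' @return `list(precision=, recall=, orientation_errors=, n_true=,
#'   n_predicted=)`. Precision is NA when nothing was predicted.
#' @export
score_against_truth <- function(scaffold_set, truth) {
  pl <- scaffold_set$placements
  unknown <- setdiff(pl$contig_id, truth$contigs$contig_id)
  if (length(unknown) > 0) stop("unknown contig id: ", unknown[1])
  pred <- list()
  for (sid in unique(pl$scaffold_id)) {
    p <- pl[pl$scaffold_id == sid, ]
    if (nrow(p) < 2) next
    a <- p[-nrow(p), ]; b <- p[-1, ]
    pred[[sid]] <- data.frame(a = a$contig_id, oa = a$orientation,
                              b = b$contig_id, ob = b$orientation,
                              stringsAsFactors = FALSE)
  }
  tr <- truth$adjacencies
  true_keys <- .adj_key(tr$contig_a, tr$orient_a, tr$contig_b, tr$orient_b)
  true_pairs <- .pair_key(tr$contig_a, tr$contig_b)
  if (length(pred) == 0)
    return(list(precision = NA_real_, recall = 0,
                orientation_errors = 0L, n_true = length(true_keys),
                n_predicted = 0L))
  pd <- do.call(rbind, pred)
  pred_keys <- .adj_key(pd$a, pd$oa, pd$b, pd$ob)
  hit <- pred_keys %in% true_keys
  pair_hit <- .pair_key(pd$a, pd$b) %in% true_pairs
  list(precision = mean(hit),
       recall = sum(unique(pred_keys) %in% true_keys) / length(true_keys),
       orientation_errors = sum(pair_hit & !hit),
       n_true = length(true_keys), n_predicted = nrow(pd))
}
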