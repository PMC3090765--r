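#' Parse a virtual-map marker table
#'
#' Reads a tab-separated marker table describing a virtual genome map: each
#' row is one marker with a chromosome assignment and a physical position in
#' bp on the map coordinate system. Positions are treated as 0-based bp.
#'
#' @param path Path to a TSV file with a header row. Required columns:
#'   `marker_id`, `chromosome`, `map_pos`; optional columns `gene_name` and
#'   `source` (one of `FISH`, `linkage`, `synteny`, `unknown`).
#' @return A data.frame with one row per marker, in file order, with columns
#'   `marker_id`, `chromosome`, `map_pos` (integer-valued numeric bp),
#'   `gene_name`, `source` (NA when absent from the file).
#' @export
parse_map_table <- function(path) {
  if (!file.exists(path)) stop("map table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker_id", "chromosome", "map_pos")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("map table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) {
    return(data.frame(marker_id = character(), chromosome = character(),
                      map_pos = numeric(), gene_name = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.numeric(tab$map_pos))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 0)
  if (length(bad) > 0)
    stop("non-numeric or negative map_pos at line ", bad[1] + 1L,
         " of ", path, " (value '", tab$map_pos[bad[1]], "')")
  dup <- tab$marker_id[duplicated(tab$marker_id)]
  if (length(dup) > 0)
    stop("duplicate marker_id in map table: ", dup[1])
  if (any(!nzchar(tab$chromosome)))
    stop("empty chromosome field at line ",
         which(!nzchar(tab$chromosome))[1] + 1L)
  data.frame(
    marker_id  = tab$marker_id,
    chromosome = tab$chromosome,
    map_pos    = pos,
    gene_name  = if ("gene_name" %in% names(tab)) tab$gene_name else NA_character_,
    source     = if ("source" %in% names(tab)) tab$source else NA_character_,
    stringsAsFactors = FALSE
  )
}

# PSL column names (standard 21-column BLAT output).
.psl_cols <- c("matches", "misMatches", "repMatches", "nCount",
               "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
               "strand", "qName", "qSize", "qStart", "qEnd",
               "tName", "tSize", "tStart", "tEnd",
               "blockCount", "blockSizes", "qStarts", "tStarts")

#' Load marker placements from BLAT PSL alignments
#'
#' Parses 21-column PSL (with or without the 5-line `psLayout` header) and
#' keeps, per marker (qName), the single highest-scoring alignment. The
#' score is BLAT's web score:
#' `matches + repMatches - misMatches - qNumInsert - tNumInsert`.
#' A marker whose top score is shared by hits on distinct contigs is
#' ambiguous and dropped (it would create false joins); equal-score hits on
#' the same contig keep the lowest tStart. PSL target coordinates are native
#' 0-based half-open and are used as-is. The placement strand is the
#' query-on-target orientation: the single PSL strand character, or the
#' product of the two characters for translated alignments.
#'
#' @param path Path to a PSL file.
#' @return A data.frame with columns `marker_id`, `contig_id`, `start`,
#'   `end`, `strand`, `score`, one row per unambiguously placed marker.
#'   Attribute `ambiguous` holds the ids of markers dropped for score ties
#'   across contigs.
#' @export
load_placements <- function(path) {
  if (!file.exists(path)) stop("PSL file not found: ", path)
  lines <- readLines(path)
  offset <- 0L
  if (length(lines) > 0 && grepl("^psLayout", lines[1])) {
    offset <- 5L                       # psLayout header is 5 lines
    lines <- lines[-seq_len(min(5L, length(lines)))]
  }
  lines <- lines[nzchar(lines)]
  empty <- data.frame(marker_id = character(), contig_id = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) {
    attr(empty, "ambiguous") <- character()
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 21L))
    stop("malformed PSL line ", which(nf != 21L)[1] + offset,
         " in ", path, ": expected 21 fields, got ", nf[nf != 21L][1])
  m <- matrix(unlist(parts), ncol = 21L, byrow = TRUE)
  colnames(m) <- .psl_cols
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("malformed PSL line ", which(is.na(v))[1] + offset,
           " in ", path, ": non-numeric ", col)
    v
  }
  strand_raw <- m[, "strand"]
  eff_strand <- vapply(strand_raw, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (!all(ch %in% c("+", "-")) || !(length(ch) %in% 1:2))
      return(NA_character_)
    if (length(ch) == 1) ch else if (ch[1] == ch[2]) "+" else "-"
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(eff_strand))
    stop("malformed PSL line ", which(is.na(eff_strand))[1] + offset,
         " in ", path, ": bad strand field")
  hits <- data.frame(
    marker_id = m[, "qName"],
    contig_id = m[, "tName"],
    start = num("tStart"),
    end = num("tEnd"),
    strand = eff_strand,
    score = num("matches") + num("repMatches") - num("misMatches") -
            num("qNumInsert") - num("tNumInsert"),
    stringsAsFactors = FALSE
  )
  # best hit per marker; deterministic tie-break within a contig by tStart
  hits <- hits[order(hits$marker_id, -hits$score, hits$contig_id, hits$start), ]
  best_score <- tapply(hits$score, hits$marker_id, max)[unique(hits$marker_id)]
  top <- hits[hits$score == best_score[hits$marker_id], ]
  n_contigs <- tapply(top$contig_id, top$marker_id,
                      function(x) length(unique(x)))
  ambiguous <- names(n_contigs)[n_contigs > 1]
  keep <- top[!(top$marker_id %in% ambiguous), ]
  keep <- keep[!duplicated(keep$marker_id), ]
  keep <- keep[order(keep$marker_id), ]
  rownames(keep) <- NULL
  attr(keep, "ambiguous") <- sort(ambiguous)
  keep
}

#' Build distance-binned pseudo mate-pair library specifications
#'
#' One library per target distance `d` in `seq(d_start, d_end, d_step)`.
#' Library `d` covers marker separations in the half-open bin
#' `[d - d_step/2, d + d_step/2)`, so bins are disjoint and contiguous and
#' each library's mean insert is exactly `d`. With the defaults (5 Mb start,
#' 10 Mb end, 1 Mb step) this yields six libraries; the 5 Mb floor reflects
#' FISH positional imprecision of a few megabases, below which marker order
#' on the map cannot be trusted.
#'
#' @param d_start,d_end,d_step Distance grid in bp. `d_start <= d_end`,
#'   `d_step > 0`.
#' @param priority Integer priority for links from these libraries
#'   (1 = highest; sequence libraries default to 1, map libraries to 2).
#' @return A data.frame of library specs: `name`, `insert_min`,
#'   `insert_max`, `insert_mean`, `priority`.
#' @export
make_pseudo_libraries <- function(d_start = 5e6, d_end = 10e6, d_step = 1e6,
                                  priority = 2L) {
  if (d_step <= 0) stop("d_step must be positive")
  if (d_start > d_end) stop("d_start must be <= d_end")
  d <- seq(d_start, d_end, by = d_step)
  libs <- data.frame(
    name = sprintf("map%gM", d / 1e6),
    insert_min = d - d_step / 2,
    insert_max = d + d_step / 2,
    insert_mean = d,
    priority = as.integer(priority),
    stringsAsFactors = FALSE
  )
  if (any(libs$insert_min <= 0))
    stop("d_start - d_step/2 must be positive")
  libs
}

#' Library spec for a sequence-based paired-end library
#'
#' @param name Library name (e.g. "pe4k").
#' @param insert_mean Nominal insert size in bp.
#' @param insert_min,insert_max Insert bounds; default +/-10% around the
#'   nominal insert.
#' @param priority Link priority (1 = highest; default 1 for sequence data).
#' @return One-row data.frame with the same columns as
#'   [make_pseudo_libraries()].
#' @export
make_seq_library <- function(name, insert_mean,
                             insert_min = round(0.9 * insert_mean),
                             insert_max = round(1.1 * insert_mean),
                             priority = 1L) {
  stopifnot(insert_min > 0, insert_min < insert_max)
  data.frame(name = name, insert_min = insert_min, insert_max = insert_max,
             insert_mean = (insert_min + insert_max) / 2,
             priority = as.integer(priority), stringsAsFactors = FALSE)
}

#' Enumerate pseudo mate-pairs from a marker map
#'
#' For every unordered pair of markers on the same chromosome whose map
#' separation falls inside a library's distance bin
#' `[insert_min, insert_max)`, emits exactly one pseudo pair assigned to
#' that library. Separations outside all bins are omitted; in particular
#' everything below the smallest bin edge, honouring the minimum-interval
#' rule for FISH-placed markers.
#'
#' @param markers Marker data.frame from [parse_map_table()].
#' @param libraries Library specs from [make_pseudo_libraries()]; their bins
#'   must be disjoint.
#' @return A data.frame of pseudo pairs: `marker_lo`, `marker_hi` (lower /
#'   higher map position; ties broken by marker id), `chromosome`,
#'   `separation` (bp) and `library`.
#' @export
enumerate_pseudo_pairs <- function(markers, libraries) {
  .check_disjoint_bins(libraries)
  out <- list()
  lib_ord <- libraries[order(libraries$insert_min), ]
  lo_edge <- min(lib_ord$insert_min)
  hi_edge <- max(lib_ord$insert_max)
  for (chrom in sort(unique(markers$chromosome))) {
    mk <- markers[markers$chromosome == chrom, ]
    mk <- mk[order(mk$map_pos, mk$marker_id), ]
    n <- nrow(mk)
    if (n < 2) next
    pos <- mk$map_pos
    # for each anchor i, candidate partners j > i with sep in [lo, hi)
    first <- findInterval(pos + lo_edge, pos, left.open = TRUE) + 1L
    last  <- findInterval(pos + hi_edge, pos, left.open = TRUE)
    # left.open on the upper bound makes sep == hi_edge fall outside
    last  <- pmin(last, n)
    cnt <- pmax(0L, last - pmax(first, seq_len(n) + 1L) + 1L)
    if (sum(cnt) == 0) next
    i_idx <- rep.int(seq_len(n), cnt)
    j_idx <- unlist(lapply(seq_len(n), function(i) {
      if (cnt[i] > 0) seq.int(max(first[i], i + 1L), last[i]) else integer()
    }), use.names = FALSE)
    sep <- pos[j_idx] - pos[i_idx]
    # assign each separation to its (disjoint) bin, if any
    bin <- rep(NA_integer_, length(sep))
    for (k in seq_len(nrow(lib_ord))) {
      inb <- sep >= lib_ord$insert_min[k] & sep < lib_ord$insert_max[k]
      bin[inb] <- k
    }
    ok <- !is.na(bin)
    if (!any(ok)) next
    out[[chrom]] <- data.frame(
      marker_lo = mk$marker_id[i_idx[ok]],
      marker_hi = mk$marker_id[j_idx[ok]],
      chromosome = chrom,
      separation = sep[ok],
      library = lib_ord$name[bin[ok]],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(marker_lo = character(), marker_hi = character(),
                      chromosome = character(), separation = numeric(),
                      library = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$marker_lo, res$marker_hi), ]
  rownames(res) <- NULL
  res
}

.check_disjoint_bins <- function(libraries) {
  stopifnot(all(c("name", "insert_min", "insert_max", "insert_mean",
                  "priority") %in% names(libraries)))
  lb <- libraries[order(libraries$insert_min), ]
  if (nrow(lb) > 1 &&
      any(lb$insert_min[-1] < lb$insert_max[-nrow(lb)]))
    stop("library bins must be disjoint")
  invisible(TRUE)
}

#' Convert pseudo pairs into inter-contig links
#'
#' Treats each pseudo pair as the two reads of a virtual long-insert
#' fragment in innie (FR) orientation: the lower-map-position marker is the
#' forward read (facing increasing map coordinate), the higher one the
#' reverse read. Composing that convention with each marker's placement
#' strand gives, per contig, the gap-facing end and the tail (bp between
#' the marker's outer edge and that end). The link's implied insert is the
#' pair's exact map separation. Pairs with an unplaced or ambiguous marker,
#' or with both markers on the same contig, are skipped and tallied.
#'
#' @param pairs Pseudo pairs from [enumerate_pseudo_pairs()].
#' @param placements Placement data.frame from [load_placements()].
#' @param libraries Library specs used to build the pairs.
#' @param contig_lengths Named numeric vector of contig lengths in bp.
#' @return `list(links = <link data.frame>, skips = <per-library tallies>)`.
#'   Links carry `read_a`/`read_b` ids for Bambus export; the skip report
#'   has per-library counts `n_pairs`, `n_links`, `unplaced`, `intra_contig`.
#' @export
pairs_to_links <- function(pairs, placements, libraries, contig_lengths) {
  skips <- data.frame(library = libraries$name, n_pairs = 0L, n_links = 0L,
                      unplaced = 0L, intra_contig = 0L,
                      stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    tab <- table(factor(pairs$library, levels = libraries$name))
    skips$n_pairs <- as.integer(tab[skips$library])
  }
  if (nrow(pairs) == 0)
    return(list(links = .empty_links(), skips = skips))

  pl <- placements
  idx_lo <- match(pairs$marker_lo, pl$marker_id)
  idx_hi <- match(pairs$marker_hi, pl$marker_id)
  unplaced <- is.na(idx_lo) | is.na(idx_hi)
  same <- !unplaced & pl$contig_id[idx_lo] == pl$contig_id[idx_hi]
  keep <- !unplaced & !same
  add_tally <- function(col, flag) {
    tab <- table(factor(pairs$library[flag], levels = libraries$name))
    skips[[col]] <<- skips[[col]] + as.integer(tab[skips$library])
  }
  add_tally("unplaced", unplaced)
  add_tally("intra_contig", same)
  if (!any(keep)) {
    skips$n_links <- 0L
    return(list(links = .empty_links(), skips = skips))
  }
  p <- pairs[keep, ]
  lo <- pl[idx_lo[keep], ]
  hi <- pl[idx_hi[keep], ]
  len_lo <- contig_lengths[lo$contig_id]
  len_hi <- contig_lengths[hi$contig_id]
  if (anyNA(len_lo) || anyNA(len_hi))
    stop("placement on contig with unknown length")
  lib_row <- match(p$library, libraries$name)
  # forward read: '+' placement faces the contig high end, tail from marker
  # start; '-' placement faces the low end, tail from marker end.
  end_a  <- ifelse(lo$strand == "+", "high", "low")
  tail_a <- ifelse(lo$strand == "+", len_lo - lo$start, lo$end)
  # reverse read: orientation composed with placement strand flips the end
  end_b  <- ifelse(hi$strand == "+", "low", "high")
  tail_b <- ifelse(hi$strand == "+", hi$end, len_hi - hi$start)
  links <- data.frame(
    library = p$library,
    priority = libraries$priority[lib_row],
    insert_mean = p$separation,
    tolerance = libraries$insert_max[lib_row] - libraries$insert_min[lib_row],
    contig_a = lo$contig_id, end_a = end_a, tail_a = as.numeric(tail_a),
    contig_b = hi$contig_id, end_b = end_b, tail_b = as.numeric(tail_b),
    read_a = paste0(p$marker_lo, "~", p$marker_hi, "/1"),
    read_b = paste0(p$marker_lo, "~", p$marker_hi, "/2"),
    stringsAsFactors = FALSE
  )
  links$gap <- estimate_gap(links)
  links <- links[order(links$library, links$read_a), ]
  rownames(links) <- NULL
  tab <- table(factor(links$library, levels = libraries$name))
  skips$n_links <- as.integer(tab[skips$library])
  list(links = links, skips = skips)
}

.empty_links <- function() {
  data.frame(library = character(), priority = integer(),
             insert_mean = numeric(), tolerance = numeric(),
             contig_a = character(), end_a = character(), tail_a = numeric(),
             contig_b = character(), end_b = character(), tail_b = numeric(),
             read_a = character(), read_b = character(), gap = numeric(),
             stringsAsFactors = FALSE)
}
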