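#' Extract inter-contig links from paired-end SAM alignments
#'
#' Converts read-pair mappings into scaffolding links with the standard
#' low-coverage filters: a pair is excluded when either mate is unmapped,
#' carries more than `max_mismatches` mismatches (SAM `NM` tag), or is
#' multi-mapping. The original pipeline filtered multi-mappers at the
#' mapper; here a read is considered multi-mapping when its primary record
#' has MAPQ 0 or when any secondary/supplementary record exists for it.
#' Pairs whose mates map to the same contig carry no inter-contig
#' information and are tallied separately. A '+'-strand mate faces the
#' high-coordinate end of its contig, a '-'-strand mate the low end (FR
#' library assumption); tails are measured from the mate's outer (5') edge.
#'
#' @param path Path to a headered SAM file; `@SQ` lines are required (contig
#'   lengths enter the gap arithmetic). Any record order is accepted.
#' @param library One-row library spec (see [make_seq_library()]).
#' @param max_mismatches Maximum `NM` per mate; default 3. A missing `NM`
#'   tag counts as 0 mismatches (logged once via a message).
#' @return `list(links = <link data.frame>, skips = <one-row tally>)` with
#'   tally columns `n_pairs`, `n_links`, `unmapped`, `mismatch`, `multimap`,
#'   `orphan`, `intra_contig`. Exclusion reasons are assessed in that order,
#'   one reason per pair, so `n_links + sum(reasons) == n_pairs`.
#' @export
parse_sam_pairs <- function(path, library, max_mismatches = 3L) {
  stopifnot(nrow(library) == 1)
  if (!file.exists(path)) stop("SAM file not found: ", path)
  contig_lengths <- .sam_sq_lengths(path)

  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  empty_tally <- data.frame(library = library$name, n_pairs = 0L,
                            n_links = 0L, unmapped = 0L, mismatch = 0L,
                            multimap = 0L, orphan = 0L, intra_contig = 0L,
                            stringsAsFactors = FALSE)
  if (n == 0) return(list(links = .empty_links(), skips = empty_tally))

  flag <- rec$flag
  secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  if (anyNA(nm[!secondary]))
    message("NM tag absent for some records; treating as 0 mismatches")
  nm[is.na(nm)] <- 0L
  mate <- ifelse(bitwAnd(flag, 0x40L) != 0L, 1L, 2L)
  key <- paste0(rec$qname, "/", mate)
  multimap_keys <- unique(key[secondary])

  pri <- !secondary
  d <- data.frame(
    qname = rec$qname[pri], mate = mate[pri],
    unmapped = bitwAnd(flag[pri], 0x4L) != 0L,
    contig = as.character(rec$rname[pri]),
    pos0 = rec$pos[pri] - 1L,          # SAM POS is 1-based
    rev = bitwAnd(flag[pri], 0x10L) != 0L,
    mapq = rec$mapq[pri], nm = nm[pri],
    cigar = rec$cigar[pri],
    multi = key[pri] %in% multimap_keys,
    stringsAsFactors = FALSE
  )
  d$ref_width <- .cigar_ref_width(d$cigar)
  d <- d[!duplicated(paste0(d$qname, "/", d$mate)), ]
  d <- d[order(d$qname, d$mate), ]

  tally <- empty_tally
  tally$n_pairs <- length(unique(d$qname))
  # pair mates side by side; qnames lacking either mate are orphans
  cnt <- table(d$qname)
  paired_qn <- names(cnt)[cnt == 2L]
  tally$orphan <- tally$n_pairs - length(paired_qn)
  dp <- d[d$qname %in% paired_qn, ]
  if (nrow(dp) == 0) return(list(links = .empty_links(), skips = tally))
  a <- dp[dp$mate == 1L, ]
  b <- dp[dp$mate == 2L, ]
  stopifnot(identical(a$qname, b$qname))

  bad_unmapped <- a$unmapped | b$unmapped
  bad_mismatch <- !bad_unmapped & (a$nm > max_mismatches | b$nm > max_mismatches)
  is_multi <- function(r) r$multi | (!is.na(r$mapq) & r$mapq == 0L)
  bad_multi <- !bad_unmapped & !bad_mismatch & (is_multi(a) | is_multi(b))
  same_ctg <- !bad_unmapped & !bad_mismatch & !bad_multi &
    a$contig == b$contig
  keep <- !bad_unmapped & !bad_mismatch & !bad_multi & !same_ctg
  tally$unmapped <- sum(bad_unmapped)
  tally$mismatch <- sum(bad_mismatch)
  tally$multimap <- sum(bad_multi)
  tally$intra_contig <- sum(same_ctg)

  if (!any(keep)) return(list(links = .empty_links(), skips = tally))
  a <- a[keep, ]; b <- b[keep, ]
  len_a <- contig_lengths[a$contig]; len_b <- contig_lengths[b$contig]
  if (anyNA(len_a) || anyNA(len_b))
    stop("SAM record on contig absent from @SQ: ",
         c(a$contig[is.na(len_a)], b$contig[is.na(len_b)])[1])
  links <- data.frame(
    library = library$name, priority = library$priority,
    insert_mean = library$insert_mean,
    tolerance = library$insert_max - library$insert_min,
    contig_a = a$contig,
    end_a = ifelse(a$rev, "low", "high"),
    tail_a = as.numeric(ifelse(a$rev, a$pos0 + a$ref_width, len_a - a$pos0)),
    contig_b = b$contig,
    end_b = ifelse(b$rev, "low", "high"),
    tail_b = as.numeric(ifelse(b$rev, b$pos0 + b$ref_width, len_b - b$pos0)),
    read_a = paste0(a$qname, "/1"), read_b = paste0(b$qname, "/2"),
    stringsAsFactors = FALSE
  )
  links$gap <- estimate_gap(links)
  links <- links[order(links$read_a), ]
  rownames(links) <- NULL
  tally$n_links <- nrow(links)
  list(links = links, skips = tally)
}

# contig name -> length from @SQ header lines; error when none present
.sam_sq_lengths <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  lens <- numeric(); nms <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "@")) break
    if (startsWith(ln, "@SQ")) {
      sn <- sub(".*\tSN:([^\t]+).*", "\\1", ln)
      lg <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", ln))
      nms <- c(nms, sn); lens <- c(lens, lg)
    }
  }
  if (length(lens) == 0)
    stop("SAM file has no @SQ header lines; contig lengths are required")
  stats::setNames(lens, nms)
}

# reference-space width of a CIGAR string (M/D/N/=/X consume reference)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_real_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}
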