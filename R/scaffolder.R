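#' Estimate the inter-contig gap implied by a link
#'
#' `gap = insert_mean - tail_a - tail_b`: the portion of the (pseudo)
#' fragment not accounted for by the two contig tails. Negative values are
#' legitimate and mean the contigs overlap.
#'
#' @param links A link data.frame (or any data.frame with numeric columns
#'   `insert_mean`, `tail_a`, `tail_b`).
#' @return Numeric vector of gap estimates in bp, one per link.
#' @export
estimate_gap <- function(links) {
  links$insert_mean - links$tail_a - links$tail_b
}

#' Bundle links supporting the same oriented contig-pair join
#'
#' Links are grouped by (canonical contig pair, gap-facing ends, priority);
#' the contig pair is canonicalised so that `contig_a < contig_b`
#' lexicographically (swapping ends and tails along). Each group becomes a
#' bundle whose weight is the link count and whose gap is the median of the
#' member gap estimates. Bundles below the minimum weight for their
#' priority are discarded: by default sequence links (priority 1) need 2
#' supporting pairs while map links (priority 2) are kept singly, because a
#' pseudo mate-pair is a curated map constraint rather than a stochastic
#' read.
#'
#' @param links Link data.frame from [pairs_to_links()] and/or
#'   [parse_sam_pairs()] (row-bind them to combine data types).
#' @param min_weight Named vector mapping priority to minimum bundle
#'   weight; default `c("1" = 2, "2" = 1)`. Priorities not named default
#'   to 1.
#' @return Bundle data.frame: `contig_a`, `end_a`, `contig_b`, `end_b`,
#'   `priority`, `weight`, `gap`, `tolerance` (largest member library
#'   insert range, floored at 1000 bp; used by the scaffolder's
#'   consistency test).
#' @export
bundle_links <- function(links, min_weight = c("1" = 2, "2" = 1)) {
  empty <- data.frame(contig_a = character(), end_a = character(),
                      contig_b = character(), end_b = character(),
                      priority = integer(), weight = integer(),
                      gap = numeric(), tolerance = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(links) || nrow(links) == 0) return(empty)
  stopifnot(all(links$contig_a != links$contig_b), all(links$tail_a >= 0),
            all(links$tail_b >= 0))
  swap <- links$contig_a > links$contig_b
  ln <- links
  for (col in c("gap", "tolerance", "tail_a", "tail_b", "insert_mean"))
    ln[[col]] <- as.numeric(ln[[col]])
  ln[swap, c("contig_a", "end_a", "tail_a", "contig_b", "end_b", "tail_b")] <-
    links[swap, c("contig_b", "end_b", "tail_b", "contig_a", "end_a", "tail_a")]
  dt <- data.table::as.data.table(ln)
  gap <- tolerance <- contig_a <- end_a <- contig_b <- end_b <-
    priority <- weight <- NULL  # NSE columns
  bd <- dt[, list(weight = .N,
                  gap = stats::median(gap),
                  tolerance = max(max(tolerance), 1000)),
           by = list(contig_a, end_a, contig_b, end_b, priority)]
  minw <- min_weight[as.character(bd$priority)]
  minw[is.na(minw)] <- 1
  bd <- bd[bd$weight >= minw, ]
  bd <- as.data.frame(bd, stringsAsFactors = FALSE)
  bd <- bd[order(bd$priority, -bd$weight, abs(bd$gap),
                 bd$contig_a, bd$contig_b, bd$end_a, bd$end_b), ]
  rownames(bd) <- NULL
  bd
}

# Relative placement implied by a bundle, in contig_a's forward frame.
# A contig's placement is the affine map T(x) = o + s*x from its own
# coordinates into the frame (s = +1/-1).  end_a faces a gap of `gap` bp,
# beyond which sits end_b of contig_b, facing back.
.bundle_rel <- function(end_a, end_b, gap, len_a, len_b) {
  if (end_a == "high") {
    if (end_b == "low") list(o = len_a + gap, s = 1)
    else                list(o = len_a + gap + len_b, s = -1)
  } else {
    if (end_b == "high") list(o = -gap - len_b, s = 1)
    else                 list(o = -gap, s = -1)
  }
}

#' Greedily order and orient contigs into scaffolds
#'
#' Bundles are applied best-first: sorted by priority (ascending, so
#' sequence-based evidence is consumed before map-based evidence), then
#' weight descending, absolute gap ascending, and lexicographic pair/end id
#' as the final tie-break, making the run fully deterministic. A
#' union-with-offset forest tracks each contig's scaffold, offset and
#' orientation. A bundle joining two scaffolds is always accepted and
#' merges them at the implied relative placement. A bundle internal to one
#' scaffold is accepted only if the implied placement agrees with the
#' stored one: same relative orientation, and offset within the bundle's
#' tolerance (the member library's insert range, at least 1000 bp).
#' Otherwise it is rejected and recorded as a conflict — this is how
#' higher-priority sequence data overrides contradicting map data, since by
#' the time map bundles are processed the sequence layout is already in
#' place. After all bundles, each tree is linearised: contigs sorted by
#' offset (ties broken by id and nudged apart), the scaffold origin shifted
#' to zero, and inter-contig gaps derived from consecutive offsets.
#'
#' @param bundles Bundle data.frame from [bundle_links()].
#' @param contig_lengths Named numeric vector of all contig lengths;
#'   contigs without any accepted bundle become singleton scaffolds.
#' @return An object of class `scaffold_set`: a list with
#'   `placements` (scaffold_id, contig_id, offset, orientation, contig_len,
#'   gap_after), `scaffolds` (scaffold_id, n_contigs, span) and
#'   `conflicts` (the rejected bundles with a `reason` column).
#' @export
greedy_scaffold <- function(bundles, contig_lengths) {
  ids <- names(contig_lengths)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(ids)
  if (nrow(bundles) > 0) {
    unknown <- setdiff(unique(c(bundles$contig_a, bundles$contig_b)), ids)
    if (length(unknown) > 0)
      stop("bundle references contig with unknown length: ", unknown[1])
  }
  parent <- seq_len(n)       # union-find with placement relative to parent
  off <- numeric(n)          # T(x) = off + sgn * x, into the parent's frame
  sgn <- rep(1, n)
  # accumulated transform maps node i's coords into its root's frame,
  # composing child-into-parent maps top-down:
  # T_p(T_c(x)) = o_p + s_p*(o_c + s_c*x).  Paths are compressed.
  find <- function(i) {
    path <- integer(0)
    while (parent[i] != i) { path <- c(path, i); i <- parent[i] }
    o <- 0; s <- 1
    for (j in rev(path)) {   # from just-below-root down to the query node
      o <- o + s * off[j]
      s <- s * sgn[j]
      parent[j] <<- i; off[j] <<- o; sgn[j] <<- s
    }
    list(root = i, o = o, s = s)
  }

  bn <- bundles
  conflicts <- list()
  if (nrow(bn) > 0) {
    ia <- match(bn$contig_a, ids); ib <- match(bn$contig_b, ids)
    for (k in seq_len(nrow(bn))) {
      rel <- .bundle_rel(bn$end_a[k], bn$end_b[k], bn$gap[k],
                         contig_lengths[ia[k]], contig_lengths[ib[k]])
      fa <- find(ia[k]); fb <- find(ib[k])
      # implied transform of b into a's root frame: T_a o rel
      o_imp <- fa$o + fa$s * rel$o
      s_imp <- fa$s * rel$s
      if (fa$root != fb$root) {
        # re-parent b's root so that b's implied placement holds:
        # U o T_b = T_imp  =>  s_U = s_imp*s_b, o_U = o_imp - s_U*o_b
        s_u <- s_imp * fb$s
        o_u <- o_imp - s_u * fb$o
        parent[fb$root] <- fa$root
        off[fb$root] <- o_u
        sgn[fb$root] <- s_u
      } else {
        if (s_imp != fb$s) {
          conflicts[[length(conflicts) + 1L]] <-
            cbind(bn[k, ], reason = "orientation")
        } else if (abs(o_imp - fb$o) > bn$tolerance[k]) {
          conflicts[[length(conflicts) + 1L]] <-
            cbind(bn[k, ], reason = "position")
        } # else consistent: accepted, no state change needed
      }
    }
  }

  # linearize each tree
  res <- lapply(seq_len(n), function(i) find(i))
  root <- vapply(res, function(x) x$root, numeric(1))
  o_abs <- vapply(res, function(x) x$o, numeric(1))
  s_abs <- vapply(res, function(x) x$s, numeric(1))
  low <- ifelse(s_abs > 0, o_abs, o_abs - contig_lengths)
  pl <- data.frame(root = root, contig_id = ids, low = low,
                   orientation = ifelse(s_abs > 0, "+", "-"),
                   contig_len = as.numeric(contig_lengths),
                   stringsAsFactors = FALSE)
  pl <- pl[order(pl$root, pl$low, pl$contig_id), ]
  # strictly increasing offsets within a scaffold; shift origin to zero
  grp <- split(seq_len(nrow(pl)), pl$root)
  # deterministic scaffold order: by smallest member contig id
  first_id <- vapply(grp, function(ix) min(pl$contig_id[ix]), character(1))
  grp <- grp[order(first_id)]
  out <- vector("list", length(grp))
  for (g in seq_along(grp)) {
    ix <- grp[[g]]
    o <- pl$low[ix] - min(pl$low[ix])
    if (length(o) > 1) {
      for (j in 2:length(o)) if (o[j] <= o[j - 1]) o[j] <- o[j - 1] + 1
    }
    gap_after <- c(o[-1] - (o[-length(o)] + pl$contig_len[ix][-length(o)]),
                   NA_real_)
    out[[g]] <- data.frame(
      scaffold_id = sprintf("scaffold%05d", g),
      contig_id = pl$contig_id[ix],
      offset = o, orientation = pl$orientation[ix],
      contig_len = pl$contig_len[ix], gap_after = gap_after,
      stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, out)
  rownames(placements) <- NULL
  span <- tapply(placements$offset + placements$contig_len,
                 placements$scaffold_id, max)
  scaf <- data.frame(scaffold_id = names(span),
                     n_contigs = as.integer(table(placements$scaffold_id)[names(span)]),
                     span = as.numeric(span), stringsAsFactors = FALSE)
  scaf <- scaf[order(scaf$scaffold_id), ]
  rownames(scaf) <- NULL
  conf <- if (length(conflicts) > 0) do.call(rbind, conflicts) else
    cbind(bn[0, ], reason = character(0))
  rownames(conf) <- NULL
  structure(list(placements = placements, scaffolds = scaf,
                 conflicts = conf),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  multi <- sum(x$scaffolds$n_contigs >= 2)
  cat("scaffold_set:", nrow(x$scaffolds), "scaffolds (",
      multi, "with >= 2 contigs ),",
      nrow(x$placements), "contigs,",
      nrow(x$conflicts), "rejected bundle(s)\n")
  invisible(x)
}

#' Re-check bundles against a finished layout
#'
#' Verifies, for each bundle, that the final linearised placements imply
#' the bundle's relative position (within its tolerance) and orientation.
#' Used to assert the scaffolder's mutual-consistency guarantee.
#'
#' @param bundles Bundle data.frame.
#' @param scaffold_set Result of [greedy_scaffold()].
#' @return Logical vector, one per bundle: satisfied by the layout or not.
#' @export
check_bundles_against_layout <- function(bundles, scaffold_set) {
  pl <- scaffold_set$placements
  row <- match(bundles$contig_a, pl$contig_id)
  rowb <- match(bundles$contig_b, pl$contig_id)
  sat <- logical(nrow(bundles))
  for (k in seq_len(nrow(bundles))) {
    pa <- pl[row[k], ]; pb <- pl[rowb[k], ]
    if (pa$scaffold_id != pb$scaffold_id) { sat[k] <- FALSE; next }
    sa <- if (pa$orientation == "+") 1 else -1
    sb <- if (pb$orientation == "+") 1 else -1
    oa <- if (sa > 0) pa$offset else pa$offset + pa$contig_len
    ob <- if (sb > 0) pb$offset else pb$offset + pb$contig_len
    rel <- .bundle_rel(bundles$end_a[k], bundles$end_b[k], bundles$gap[k],
                       pa$contig_len, pb$contig_len)
    o_imp <- oa + sa * rel$o
    s_imp <- sa * rel$s
    sat[k] <- (s_imp == sb) && abs(o_imp - ob) <= bundles$tolerance[k]
  }
  sat
}

#' Write a scaffold layout as AGP v2.0 plus a raw layout TSV
#'
#' AGP gap rows cannot carry non-positive lengths, so gaps are floored at
#' 20 bp in the AGP (and in any FASTA rendered from it); the raw, possibly
#' negative, gap estimates are preserved in the side-car `<prefix>.layout.tsv`.
#'
#' @param scaffold_set Result of [greedy_scaffold()].
#' @param prefix Output path prefix; writes `<prefix>.agp` and
#'   `<prefix>.layout.tsv`.
#' @return Invisibly, the AGP path.
#' @export
write_agp <- function(scaffold_set, prefix) {
  pl <- scaffold_set$placements
  lines <- character(0)
  for (sid in unique(pl$scaffold_id)) {
    p <- pl[pl$scaffold_id == sid, ]
    part <- 0L; cur <- 0
    for (i in seq_len(nrow(p))) {
      if (i > 1) {
        gap <- max(20, round(p$gap_after[i - 1]))
        part <- part + 1L
        lines <- c(lines, paste(sid, cur + 1, cur + gap, part, "N", gap,
                                "scaffold", "yes", "paired-ends", sep = "\t"))
        cur <- cur + gap
      }
      part <- part + 1L
      lines <- c(lines, paste(sid, cur + 1, cur + p$contig_len[i], part, "W",
                              p$contig_id[i], 1, p$contig_len[i],
                              p$orientation[i], sep = "\t"))
      cur <- cur + p$contig_len[i]
    }
  }
  agp <- paste0(prefix, ".agp")
  writeLines(c("##agp-version\t2.0", lines), agp)
  data.table::fwrite(pl, paste0(prefix, ".layout.tsv"), sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(agp)
}

#' Render scaffold sequences from a layout
#'
#' Gaps become 'N' runs, floored at 20 so the FASTA stays syntactically
#' meaningful even for negative gap estimates; '-' contigs are
#' reverse-complemented.
#'
#' @param scaffold_set Result of [greedy_scaffold()].
#' @param contigs A [Biostrings::DNAStringSet] of contig sequences.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_scaffold_fasta <- function(scaffold_set, contigs, path) {
  pl <- scaffold_set$placements
  seqs <- vapply(unique(pl$scaffold_id), function(sid) {
    p <- pl[pl$scaffold_id == sid, ]
    pieces <- character(0)
    for (i in seq_len(nrow(p))) {
      s <- contigs[[p$contig_id[i]]]
      if (p$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      if (i > 1)
        pieces <- c(pieces, strrep("N", max(20, round(p$gap_after[i - 1]))))
      pieces <- c(pieces, as.character(s))
    }
    paste0(pieces, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- unique(pl$scaffold_id)
  Biostrings::writeXStringSet(out, path, width = 80L)
  invisible(path)
}
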