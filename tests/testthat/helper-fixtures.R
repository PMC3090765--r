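# Small in-code fixture builders and independent oracles shared by tests.

write_map_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("marker_id\tchromosome\tmap_pos\tgene_name\tsource", rows),
             path)
  path
}

# one 21-column PSL line from the fields that matter; everything else zeroed
psl_line <- function(qName, tName, tStart, tEnd, matches,
                     misMatches = 0, repMatches = 0, qNumInsert = 0,
                     tNumInsert = 0, strand = "+", tSize = 1e6) {
  paste(matches, misMatches, repMatches, 0, qNumInsert, 0, tNumInsert, 0,
        strand, qName, tEnd - tStart, 0, tEnd - tStart, tName, tSize,
        tStart, tEnd, 1, paste0(tEnd - tStart, ","), "0,",
        paste0(tStart, ","), sep = "\t")
}

write_psl <- function(lines, path = tempfile(fileext = ".psl")) {
  writeLines(lines, path)
  path
}

# minimal SAM builder: recs is a list of lists with qname, flag, rname,
# pos (1-based), mapq, cigar, rnext, pnext, tags (character, e.g. "NM:i:2")
write_sam <- function(recs, sq = c(c1 = 10000, c2 = 10000),
                      path = tempfile(fileext = ".sam"), header = TRUE) {
  lines <- character(0)
  if (header)
    lines <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  body <- vapply(recs, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq %||% 60,
          r$cigar %||% "100M", r$rnext %||% "*", r$pnext %||% 0, 0, "*", "*",
          r$tags %||% "NM:i:0", sep = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FR pair builder: mate1 forward on rname1 at pos1, mate2 reverse on rname2
sam_pair <- function(qname, rname1, pos1, rname2, pos2,
                     mapq1 = 60, mapq2 = 60, nm1 = 0, nm2 = 0,
                     flag1 = 0x1 + 0x40, flag2 = 0x1 + 0x80 + 0x10) {
  list(
    list(qname = qname, flag = flag1, rname = rname1, pos = pos1,
         mapq = mapq1, tags = sprintf("NM:i:%d", nm1)),
    list(qname = qname, flag = flag2, rname = rname2, pos = pos2,
         mapq = mapq2, tags = sprintf("NM:i:%d", nm2))
  )
}

# O(n^2) brute-force pseudo-pair oracle, written independently of the
# package's windowed enumeration: all unordered same-chromosome pairs,
# binned by plain comparison against each library's [min, max).
oracle_pseudo_pairs <- function(markers, libraries) {
  out <- list()
  for (i in seq_len(nrow(markers))) {
    for (j in seq_len(nrow(markers))) {
      if (j <= i) next
      if (markers$chromosome[i] != markers$chromosome[j]) next
      sep <- abs(markers$map_pos[i] - markers$map_pos[j])
      lib <- NA_character_
      for (k in seq_len(nrow(libraries))) {
        if (sep >= libraries$insert_min[k] && sep < libraries$insert_max[k])
          lib <- libraries$name[k]
      }
      if (is.na(lib)) next
      lo <- if (markers$map_pos[i] < markers$map_pos[j] ||
                (markers$map_pos[i] == markers$map_pos[j] &&
                 markers$marker_id[i] < markers$marker_id[j])) i else j
      hi <- if (lo == i) j else i
      out[[length(out) + 1L]] <- data.frame(
        marker_lo = markers$marker_id[lo], marker_hi = markers$marker_id[hi],
        separation = sep, library = lib, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(marker_lo = character(), marker_hi = character(),
                      separation = numeric(), library = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

random_map <- function(n, chr_len = 30e6, n_chrom = 2) {
  data.frame(
    marker_id = sprintf("R%04d", seq_len(n)),
    chromosome = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    map_pos = round(runif(n, 0, chr_len)),
    gene_name = NA_character_, source = NA_character_,
    stringsAsFactors = FALSE)
}

# independent n50 oracle: running total over the sorted list, no vector ops
oracle_n50 <- function(spans) {
  s <- sort(spans, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# independent re-derivation of the relative placement a bundle implies,
# used to brute-force small layouts (mirrors the innie/FR geometry, not the
# package code): returns b's (origin, sign) in a's forward frame
oracle_rel <- function(end_a, end_b, gap, len_a, len_b) {
  if (end_a == "high" && end_b == "low")  return(c(len_a + gap, 1))
  if (end_a == "high" && end_b == "high") return(c(len_a + gap + len_b, -1))
  if (end_a == "low" && end_b == "high")  return(c(-gap - len_b, 1))
  c(-gap, -1)
}

# derive the bundle that a true adjacent placement implies (a left of b in
# a common frame; `off_*` are low-end offsets, `or_*` orientations) — for
# building conflict-free instances from a random true layout
bundle_from_layout <- function(a, off_a, or_a, len_a,
                               b, off_b, or_b, len_b, priority = 1L,
                               weight = 3L, tolerance = 1000) {
  end_a <- if (or_a == "+") "high" else "low"   # a faces the gap rightward
  end_b <- if (or_b == "+") "low" else "high"   # b faces it leftward
  data.frame(contig_a = a, end_a = end_a, contig_b = b, end_b = end_b,
             priority = priority, weight = weight,
             gap = off_b - (off_a + len_a), tolerance = tolerance,
             stringsAsFactors = FALSE)
}

# canonicalise a bundle data.frame the way bundle_links does
canon_bundles <- function(bd) {
  swap <- bd$contig_a > bd$contig_b
  out <- bd
  out[swap, c("contig_a", "end_a", "contig_b", "end_b")] <-
    bd[swap, c("contig_b", "end_b", "contig_a", "end_a")]
  out
}
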