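# Shared fixtures: tiny genomes, a hand-built SAM, and brute-force oracles.

tiny_genome <- function() {
  genome_def(c("1A", "1B"), c(250e6, 80e6), c(110e6, NA))
}

# genome definition TSV on disk
write_tiny_genome_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("# toy genome",
               "chrom\tlength\tcentromere",
               "1A\t594102056\t213000000",
               "1B\t689851870\t",
               "2A\t780798557\t339000000"), path)
  path
}

# Brute-force bin enumeration oracle: starts 0, step, 2*step, ... < length.
oracle_bins <- function(len, bin, step) {
  starts <- c()
  s <- 0
  while (s < len) { starts <- c(starts, s); s <- s + step }
  data.frame(start = starts, end = pmin(starts + bin, len))
}

# Brute-force membership count oracle for count_bins.
oracle_counts <- function(pos_by_sample, bins) {
  sapply(pos_by_sample, function(tab) {
    vapply(seq_len(nrow(bins)), function(b) {
      p <- tab$pos[tab$chrom == bins$chrom[b]]
      sum(p >= bins$start[b] & p < bins$end[b])
    }, numeric(1))
  })
}

# A 30-record SAM with a known mix of unique / multimapped / unmapped /
# secondary / supplementary / scaffold records. Returns the path and the
# expected retained (chrom, pos0) table.
sam_fixture <- function(path = tempfile(fileext = ".sam")) {
  g <- tiny_genome()
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           "@SQ\tSN:1A\tLN:250000000",
           "@SQ\tSN:1B\tLN:80000000",
           "@SQ\tSN:scaffold_1177\tLN:500000")
  seq10 <- strrep("C", 10)
  mk <- function(qname, flag, rname, pos, extra = "") {
    paste0(qname, "\t", flag, "\t", rname, "\t", sprintf("%d", as.integer(pos)),
           "\t40\t10M\t*\t0\t0\t", seq10, "\t*",
           if (nzchar(extra)) paste0("\t", extra) else "")
  }
  recs <- character(0)
  keep <- list()
  for (i in 1:12) {   # unique, anchored -> retained
    pos <- i * 1000000
    chr <- if (i %% 2 == 0) "1A" else "1B"
    recs <- c(recs, mk(sprintf("u%02d", i), 0, chr, pos, "AS:i:0\tNM:i:0"))
    keep[[length(keep) + 1]] <- data.frame(chrom = chr, pos = pos - 1)
  }
  for (i in 1:6)      # XS:i present -> dropped
    recs <- c(recs, mk(sprintf("m%02d", i), 0, "1A", 5e6 + i,
                       sprintf("AS:i:0\tXS:i:%d", i)))
  for (i in 1:4)      # unmapped -> dropped
    recs <- c(recs, paste0(sprintf("x%02d", i),
                           "\t4\t*\t0\t0\t*\t*\t0\t0\t", seq10, "\t*"))
  for (i in 1:3)      # unanchored scaffold -> dropped
    recs <- c(recs, mk(sprintf("s%02d", i), 0, "scaffold_1177", 100 + i))
  for (i in 1:3)      # secondary -> dropped
    recs <- c(recs, mk(sprintf("sec%02d", i), 256, "1A", 7e6 + i))
  for (i in 1:2)      # supplementary -> dropped
    recs <- c(recs, mk(sprintf("sup%02d", i), 2048, "1B", 8e6 + i))
  writeLines(c(hdr, recs), path)
  list(path = path, genome = g, n_records = length(recs),
       expected = do.call(rbind, keep), lines = recs)
}

# grep-style oracle over raw SAM body lines
oracle_sam_filter <- function(lines, genome) {
  f <- do.call(rbind, lapply(strsplit(lines, "\t"), function(x) {
    data.frame(flag = as.integer(x[2]), rname = x[3],
               pos = as.integer(x[4]),
               has_xs = any(grepl("^XS:i:", x[-(1:11)])),
               stringsAsFactors = FALSE)
  }))
  ok <- bitwAnd(f$flag, 4L) == 0 & bitwAnd(f$flag, 256L) == 0 &
    bitwAnd(f$flag, 2048L) == 0 & !f$has_xs & f$rname %in% genome$chrom &
    f$pos >= 1
  data.frame(chrom = f$rname[ok], pos = f$pos[ok] - 1,
             stringsAsFactors = FALSE)
}

# quick euploid cohort on a small genome for normalization tests
euploid_specs <- function(n, prefix = "eu") {
  lapply(seq_len(n), function(i) aberration_spec(sprintf("%s%02d", prefix, i)))
}

# hand-built dosage track from a vector of classes (one chromosome)
track_from_classes <- function(classes, genome, chrom = genome$chrom[1],
                               bin = 10e6, step = 5e6) {
  bins <- make_bins(genome, bin, step)
  bins <- bins[bins$chrom == chrom, ][seq_along(classes), ]
  value <- c(0.1, 0.5, 1, 1.5, 2, 2.5, 3)[classes + 1]
  value[is.na(classes)] <- NA
  structure(data.frame(chrom = bins$chrom, start = bins$start,
                       end = bins$end, index = bins$index,
                       normalized = value, dosage = classes,
                       stringsAsFactors = FALSE),
            sample_id = "hand", class = c("dosage_track", "data.frame"))
}
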