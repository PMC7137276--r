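#' Aberration specifications for the tag simulator
#'
#' Describes one simulated sample as copy-number multipliers relative to the
#' disomic baseline: multiplier 1.0 is disomic (2 copies), 0 nullisomic /
#' deleted, 0.5 monosomic or heterozygous deletion, 1.5 trisomic, 2.0
#' tetrasomic. A multiplier applies either genome-wide (`default_multiplier`)
#' or over regions; regions may not overlap within one sample.
#'
#' @param sample_id sample name.
#' @param default_multiplier genome-wide baseline multiplier (default 1).
#' @param regions optional data frame `chrom`, `start`, `end`, `multiplier`
#'   (bp, 0-based half-open; `NA` start/end mean the whole chromosome).
#' @param genome optional [genome_def] used to validate region bounds.
#' @return An `aberration_spec` object.
#' @export
aberration_spec <- function(sample_id, default_multiplier = 1,
                            regions = NULL, genome = NULL) {
  if (default_multiplier < 0) stop("multipliers must be >= 0")
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), multiplier = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    regions <- as.data.frame(regions, stringsAsFactors = FALSE)
    need <- c("chrom", "multiplier")
    if (!all(need %in% names(regions)))
      stop("regions need columns chrom and multiplier")
    if (is.null(regions$start)) regions$start <- NA_real_
    if (is.null(regions$end)) regions$end <- NA_real_
    if (any(regions$multiplier < 0)) stop("multipliers must be >= 0")
    if (!is.null(genome)) {
      m <- match(regions$chrom, genome$chrom)
      if (anyNA(m)) stop("region chromosome not in genome: ",
                         paste(regions$chrom[is.na(m)], collapse = ", "))
      len <- genome$length[m]
      regions$start[is.na(regions$start)] <- 0
      regions$end[is.na(regions$end)] <- len[is.na(regions$end)]
      if (any(regions$start < 0 | regions$end > len |
              regions$start >= regions$end))
        stop("region outside chromosome bounds in sample ", sample_id)
    } else {
      regions$start[is.na(regions$start)] <- 0
      regions$end[is.na(regions$end)] <- Inf
    }
    # reject overlaps within a chromosome
    for (chr in unique(regions$chrom)) {
      r <- regions[regions$chrom == chr, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
        stop("overlapping aberration regions on ", chr,
             " in sample ", sample_id)
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 default_multiplier = default_multiplier,
                 regions = regions),
            class = "aberration_spec")
}

# per-site multiplier lookup for one spec
site_multipliers <- function(sites, spec) {
  m <- rep(spec$default_multiplier, nrow(sites))
  r <- spec$regions
  if (nrow(r)) {
    for (k in seq_len(nrow(r))) {
      hit <- sites$chrom == r$chrom[k] & sites$pos >= r$start[k] &
        sites$pos < r$end[k]
      m[hit] <- r$multiplier[k]
    }
  }
  m
}

#' Place GBS tag sites on a genome
#'
#' GBS samples a genome at restriction-enzyme cut sites, which are a fixed
#' property of the genome: every sample observes (a subset of) the same site
#' list. Sites are placed uniformly per chromosome at the given density,
#' then thinned near centromeres: methylation-sensitive GBS enzymes cut
#' rarely in centromeric heterochromatin, so a site within
#' `centromere_radius_bp` of an annotated centromere is retained with
#' probability `1 - centromere_depletion`.
#'
#' @param genome a [genome_def].
#' @param site_density expected sites per Mb (default 32, matching roughly
#'   one uniquely-anchored 64 bp tag per 31 kb of genome).
#' @param centromere_depletion fraction of centromeric sites lost, in
#'   `[0, 1]` (default 0.8).
#' @param centromere_radius_bp half-width of the depleted window (default
#'   25 Mb; scale together with the genome).
#' @param seed RNG seed; fixed seed gives an identical site list.
#' @return Data frame `chrom`, `pos` (0-based), sorted by chromosome then
#'   position.
#' @export
place_tag_sites <- function(genome, site_density = 32,
                            centromere_depletion = 0.8,
                            centromere_radius_bp = 25e6, seed = 1) {
  stopifnot(inherits(genome, "genome_def"))
  if (site_density <= 0) stop("site_density must be > 0")
  if (centromere_depletion < 0 || centromere_depletion > 1)
    stop("centromere_depletion must be in [0, 1]")
  set.seed(seed)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    n <- stats::rpois(1, site_density * len / 1e6)
    if (n == 0) {
      warning("no tag sites placed on ", genome$chrom[i],
              " at density ", site_density)
      return(NULL)
    }
    pos <- sort(floor(stats::runif(n, 0, len)))
    cen <- genome$centromere[i]
    if (!is.na(cen) && centromere_depletion > 0) {
      near <- abs(pos - cen) <= centromere_radius_bp
      drop <- near & stats::runif(n) < centromere_depletion
      pos <- pos[!drop]
    }
    data.frame(chrom = genome$chrom[i], pos = pos, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate one sample's observed tags
#'
#' Each sample observes each site independently with probability
#' `min(1, base_rate * depth_factor * multiplier(site))`, where `base_rate =
#' mean_tags / n_sites` calibrates the expected euploid total to
#' `mean_tags`, `depth_factor` is a per-sample log-normal draw
#' (`meanlog = -dispersion^2/2`, so its mean is 1) emulating the heavy
#' skew of real per-sample tag totals across sequencing batches, and the
#' multiplier comes from the sample's [aberration_spec()].
#'
#' @param sites site list from [place_tag_sites()].
#' @param spec an [aberration_spec()].
#' @param mean_tags expected retained tags for an average-depth euploid
#'   sample (default 100,000).
#' @param dispersion log-normal sd of the per-sample depth factor
#'   (default 0.5).
#' @param seed RNG seed.
#' @return A [tag_table] of observed tags.
#' @export
simulate_sample <- function(sites, spec, mean_tags = 1e5, dispersion = 0.5,
                            seed = 1) {
  stopifnot(inherits(spec, "aberration_spec"))
  if (mean_tags <= 0) stop("mean_tags must be > 0")
  set.seed(seed)
  depth <- stats::rlnorm(1, meanlog = -dispersion^2 / 2, sdlog = dispersion)
  base_rate <- mean_tags / nrow(sites)
  p <- pmin(1, base_rate * depth * site_multipliers(sites, spec))
  obs <- stats::runif(nrow(sites)) < p
  tag_table(spec$sample_id, sites$chrom[obs], sites$pos[obs])
}

#' Simulate a cohort with known dosage truth
#'
#' Generates one [tag_table] per aberration spec plus a truth table giving
#' the true copy number (2 x effective multiplier) for every bin of the
#' supplied grid. Bins straddling a region boundary get the length-weighted
#' majority multiplier. The per-bin median normalization assumes most
#' samples are disomic at any bin; a warning is emitted if more than half
#' the cohort is aberrant at some bin.
#'
#' @param genome a [genome_def].
#' @param specs list of [aberration_spec()]s (unique sample ids).
#' @param bins `karyo_bins` grid used for the truth table (defaults to
#'   [make_bins()] on the genome with its default sizes).
#' @param site_density,centromere_depletion,centromere_radius_bp passed to
#'   [place_tag_sites()].
#' @param mean_tags,dispersion passed to [simulate_sample()].
#' @param seed master seed; per-sample seeds are derived from it, so a fixed
#'   seed reproduces the cohort byte-for-byte.
#' @return List with `tags` (list of [tag_table]s), `truth` (bins x samples
#'   integer-ish matrix of copy numbers), `bins`, `sites`, and `manifest`
#'   (all parameters and derived seeds).
#' @export
simulate_cohort <- function(genome, specs, bins = NULL,
                            site_density = 32, centromere_depletion = 0.8,
                            centromere_radius_bp = 25e6,
                            mean_tags = 1e5, dispersion = 0.5, seed = 1) {
  stopifnot(inherits(genome, "genome_def"), length(specs) > 0)
  ids <- vapply(specs, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(bins)) bins <- make_bins(genome)
  sites <- place_tag_sites(genome, site_density, centromere_depletion,
                           centromere_radius_bp, seed = seed)
  sample_seeds <- (as.integer(seed) + 7919L * seq_along(specs)) %%
    .Machine$integer.max
  tags <- mapply(function(sp, sd) {
    simulate_sample(sites, sp, mean_tags = mean_tags,
                    dispersion = dispersion, seed = sd)
  }, specs, sample_seeds, SIMPLIFY = FALSE)
  truth <- vapply(specs, function(sp) truth_for_bins(bins, sp, genome),
                  numeric(nrow(bins)))
  truth <- matrix(truth, nrow = nrow(bins))   # keep shape for 1-bin grids
  colnames(truth) <- ids
  aberrant_frac <- rowMeans(truth != 2)
  if (any(aberrant_frac > 0.5))
    warning("more than half the cohort is aberrant at ",
            sum(aberrant_frac > 0.5), " bin(s); the per-bin median ",
            "normalization assumption is broken there")
  manifest <- list(seed = seed, sample_seeds = as.list(
                     stats::setNames(sample_seeds, ids)),
                   site_density = site_density,
                   centromere_depletion = centromere_depletion,
                   centromere_radius_bp = centromere_radius_bp,
                   mean_tags = mean_tags, dispersion = dispersion,
                   n_sites = nrow(sites),
                   bin_size = attr(bins, "bin_size"),
                   step_size = attr(bins, "step_size"))
  list(tags = tags, truth = truth, bins = bins, sites = sites,
       manifest = manifest)
}

# true copy number per bin: 2 x length-weighted majority multiplier
truth_for_bins <- function(bins, spec, genome) {
  vapply(seq_len(nrow(bins)), function(b) {
    chr <- bins$chrom[b]; s <- bins$start[b]; e <- bins$end[b]
    r <- spec$regions
    r <- r[r$chrom == chr & r$start < e & r$end > s, , drop = FALSE]
    if (nrow(r) == 0) return(2 * spec$default_multiplier)
    cover <- pmin(r$end, e) - pmax(r$start, s)
    rest <- (e - s) - sum(cover)
    mults <- c(r$multiplier, spec$default_multiplier)
    w <- c(cover, rest)
    2 * mults[which.max(w)]
  }, numeric(1))
}

#' Write simulated tags as a SAM file
#'
#' Emits each observed tag as a mapped, primary, `XS:i`-free 64 bp record;
#' optionally a fraction of extra multimapper records carrying `XS:i` (to
#' exercise the ingest filter) and of unanchored-scaffold records.
#'
#' @param tags a [tag_table].
#' @param genome a [genome_def] (provides `@SQ` header lines).
#' @param path output SAM path.
#' @param multimapper_rate fraction of extra `XS:i`-tagged records appended
#'   (default 0).
#' @param seed RNG seed for the multimapper positions.
#' @return `path`, invisibly.
#' @export
write_sam <- function(tags, genome, path, multimapper_rate = 0, seed = 1) {
  stopifnot(inherits(tags, "tag_table"), inherits(genome, "genome_def"))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom,
                   as.integer(genome$length)))
  rec <- tags$records
  seq64 <- strrep("A", 64)
  body <- if (nrow(rec)) sprintf(
    "%s_tag%06d\t0\t%s\t%d\t42\t64M\t*\t0\t0\t%s\t*",
    tags$sample_id, seq_len(nrow(rec)), rec$chrom,
    as.integer(rec$pos + 1), seq64) else character(0)
  extra <- character(0)
  if (multimapper_rate > 0 && nrow(rec)) {
    set.seed(seed)
    n_extra <- stats::rbinom(1, nrow(rec), multimapper_rate)
    if (n_extra > 0) {
      i <- sample.int(nrow(genome), n_extra, replace = TRUE)
      pos <- floor(stats::runif(n_extra, 0, genome$length[i])) + 1
      extra <- sprintf(
        "%s_multi%06d\t0\t%s\t%d\t3\t64M\t*\t0\t0\t%s\t*\tAS:i:0\tXS:i:0",
        tags$sample_id, seq_len(n_extra), genome$chrom[i], as.integer(pos),
        seq64)
    }
  }
  writeLines(c(hdr, body, extra), path)
  invisible(path)
}

#' Read / write aberration specs as TSV
#'
#' TSV with columns `sample`, `chrom`, `start`, `end`, `multiplier`; one row
#' per region; a row with empty `chrom` sets the sample's genome-wide
#' default multiplier; samples listed with no rows beyond a default row (or
#' with multiplier 1) are euploid.
#'
#' @param path TSV path.
#' @param genome optional [genome_def] for bounds validation.
#' @return List of [aberration_spec()]s.
#' @export
read_aberration_specs <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "multiplier") %in% names(df)))
    stop("aberration spec TSV needs columns sample and multiplier")
  if (is.null(df$chrom)) df$chrom <- ""
  lapply(unique(df$sample), function(s) {
    d <- df[df$sample == s, , drop = FALSE]
    is_default <- is.na(d$chrom) | !nzchar(d$chrom)
    def <- if (any(is_default)) d$multiplier[is_default][1] else 1
    reg <- d[!is_default, intersect(c("chrom", "start", "end", "multiplier"),
                                    names(d)), drop = FALSE]
    aberration_spec(s, default_multiplier = def,
                    regions = if (nrow(reg)) reg else NULL, genome = genome)
  })
}

#' Write the simulation truth table
#'
#' @param truth truth matrix from [simulate_cohort()].
#' @param bins the matching bin grid.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, bins, path) {
  write_bin_matrix(bins, colnames(truth), truth, path)
}
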