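#' Focal copy-number control sites on pBR322
#'
#' The ten 1-based pBR322 positions where copy-number-affecting single
#' nucleotide variants cluster: 3,027-3,035 (loop II' of the RNAI
#' replication inhibitor) and 3,118 (the -35 promoter region of the RNAII
#' replication primer precursor).
#'
#' @return Integer vector of the ten focal positions.
#' @export
focal_site_set <- function() {
  c(3027:3035, 3118L)
}

.variant_cols <- c("replicate", "time_point_hours", "position", "ref", "alt",
                   "family_count", "dcs_depth")

.validate_variant_table <- function(tab) {
  miss <- setdiff(.variant_cols, names(tab))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$dcs_depth <= 0))
    stop("invalid record: dcs_depth must be positive")
  if (any(tab$family_count < 0 | tab$family_count > tab$dcs_depth))
    stop("invalid record: need 0 <= family_count <= dcs_depth")
  tab[, .variant_cols]
}

#' Read / write a duplex-sequencing variant table
#'
#' The native format is TSV with header columns
#' `replicate, time_point_hours, position, ref, alt, family_count,
#' dcs_depth`. Positions are 1-based pBR322 coordinates; `family_count` is
#' the number of duplex consensus families supporting the variant and
#' `dcs_depth` the duplex consensus depth at the site, so the allele
#' frequency is `family_count / dcs_depth`.
#'
#' @param path File path.
#' @return `read_variant_table` returns a validated data frame;
#'   `write_variant_table` returns `path` invisibly.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(replicate = "character",
                                          ref = "character",
                                          alt = "character"))
  .validate_variant_table(tab)
}

#' @param tab A variant table data frame.
#' @rdname read_variant_table
#' @export
write_variant_table <- function(tab, path) {
  tab <- .validate_variant_table(tab)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a minimal VCF-like variant file
#'
#' Accepts a tab-separated VCF-like dialect with columns
#' `CHROM POS ID REF ALT QUAL FILTER INFO` (header lines starting with `#`
#' are skipped). INFO keys are mapped as: `DP` to `dcs_depth`, `AC` to
#' `family_count`, and optionally `TP` to `time_point_hours` (default
#' `default_hours`) and `RUN` to `replicate` (default `default_replicate`).
#' This is a convenience importer for the dialect, not a general VCF parser.
#'
#' @param path File path.
#' @param default_replicate Replicate label used when `RUN=` is absent.
#' @param default_hours Time point used when `TP=` is absent.
#' @return A variant table data frame in the native column layout.
#' @export
read_variant_vcf <- function(path, default_replicate = "R1",
                             default_hours = 0) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no variant records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L))
    stop("VCF-like records need 8 tab-separated columns")
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  rows <- lapply(fields, function(f) {
    info <- f[8L]
    dp <- info_get(info, "DP")
    ac <- info_get(info, "AC")
    if (is.na(dp) || is.na(ac))
      stop("INFO must carry DP= and AC= for every record")
    tp <- info_get(info, "TP")
    run <- info_get(info, "RUN")
    data.frame(
      replicate = if (is.na(run)) default_replicate else run,
      time_point_hours = if (is.na(tp)) default_hours else as.numeric(tp),
      position = as.integer(f[2L]), ref = f[4L], alt = f[5L],
      family_count = as.integer(ac), dcs_depth = as.integer(dp))
  })
  .validate_variant_table(do.call(rbind, rows))
}

#' Empirical mutant frequency at one time point
#'
#' The observed mutant-plasmid fraction is the sum of allele frequencies
#' (`family_count / dcs_depth`) over single-nucleotide variants at the
#' focal copy-number control sites. Records at non-focal positions
#' ("flickering" sites, sporadic single-family calls treated as drift
#' noise) and indel records are excluded. Multiple alternate alleles at one
#' focal site are summed. The sum is clamped at 1 with a warning if
#' exceeded, which cannot happen in the frequency regime the experiment
#' operates in (all frequencies well below 1).
#'
#' @param records Variant table rows sharing one replicate and time point.
#' @return Mutant frequency `x` in `[0, 1]`.
#' @export
empirical_mutant_frequency <- function(records) {
  records <- .validate_variant_table(records)
  if (nrow(records) == 0L) return(0)
  if (length(unique(records$time_point_hours)) > 1L ||
      length(unique(records$replicate)) > 1L)
    stop("records must share a single replicate and time point")
  snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref != records$alt
  focal <- records$position %in% focal_site_set() & snv
  x <- sum(records$family_count[focal] / records$dcs_depth[focal])
  if (x > 1) {
    warning("summed focal frequencies exceed 1; clamping")
    x <- 1
  }
  x
}

#' Build an observed series from a variant table
#'
#' Computes the empirical mutant frequency per time point for one replicate
#' and converts sampling hours to generation indices. Replicates are never
#' pooled: each yields its own series. Time points present in the table
#' only as flickering records still contribute a point (frequency 0).
#'
#' @param tab A variant table.
#' @param replicate Replicate label to extract.
#' @param generation_time_min Generation time used for the hours-to-
#'   generations conversion (default 60 minutes).
#' @return An [observed_series()].
#' @export
variant_series <- function(tab, replicate, generation_time_min = 60) {
  tab <- .validate_variant_table(tab)
  tab <- tab[tab$replicate == replicate, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no records for replicate ", replicate)
  hours <- sort(unique(tab$time_point_hours))
  freqs <- vapply(hours, function(h) {
    empirical_mutant_frequency(tab[tab$time_point_hours == h, , drop = FALSE])
  }, numeric(1))
  observed_series(hours_to_generations(hours, generation_time_min), freqs)
}

#' Convert sampling hours to generation indices
#'
#' @param hours Sampling time in hours (vectorized, `>= 0`).
#' @param generation_time_min Generation time in minutes (default 60, the
#'   value assumed when modeling the turbidostat runs).
#' @return Nearest-integer generation indices.
#' @export
hours_to_generations <- function(hours, generation_time_min = 60) {
  if (generation_time_min <= 0) stop("generation time must be positive")
  if (any(hours < 0)) stop("hours must be non-negative")
  as.integer(round(hours * 60 / generation_time_min))
}

#' Maximum growth rate from an optical-density rise
#'
#' The turbidostat growth-rate proxy: the steepest part of the growth curve
#' is the rise of OD600 from 0.6 to 0.8, so the maximum growth rate is
#' `ln(0.8 / 0.6) / t` for a rise lasting `t` minutes.
#'
#' @param t_minutes Duration of the OD600 0.6 to 0.8 rise, in minutes.
#' @return Growth rate per minute.
#' @export
max_growth_rate <- function(t_minutes) {
  if (any(t_minutes <= 0)) stop("rise duration must be positive")
  log(0.8 / 0.6) / t_minutes
}

#' Generation time from a growth rate
#'
#' @param rate Growth rate per minute (`> 0`).
#' @return Generation (doubling) time in minutes, `ln(2) / rate`.
#' @export
generation_time <- function(rate) {
  if (any(rate <= 0)) stop("growth rate must be positive")
  log(2) / rate
}
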