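#' TauI RFLP fragment pattern for FADS2 rs174583
#'
#' The amplicon spans 572 bp. The C (wild-type) allele carries the TauI
#' restriction site and is cleaved into 192 and 380 bp fragments; the T
#' (minor) allele is uncut and runs as the full 572 bp band. The two
#' cleavage products therefore sum to the amplicon length.
#'
#' @return List with `amplicon` (572) and `cut_fragments` (c(192, 380)).
#' @export
rflp_fragments_rs174583 <- function() {
  list(amplicon = 572, cut_fragments = c(192, 380))
}

.rflp_patterns <- function() {
  frag <- rflp_fragments_rs174583()
  list(CC = sort(frag$cut_fragments),
       TT = frag$amplicon,
       CT = sort(c(frag$cut_fragments, frag$amplicon)))
}

#' Call a genotype from RFLP fragment lengths
#'
#' Matches each observed band to the nearest expected fragment length
#' within `tolerance` base pairs (emulating gel resolution) and reads the
#' genotype off the matched pattern: {192, 380} is CC, {572} is TT, and
#' all three bands together are CT. Any unmatched band, or a matched set
#' that is none of the three canonical patterns, is uncallable.
#'
#' @param fragments Numeric vector of observed band lengths in bp.
#' @param tolerance Matching tolerance in bp (default 10).
#' @return A list of class `gx_genotype_call` with `genotype`, `alleles`
#'   and `evidence` (observed length, matched expected length).
#' @export
call_genotype <- function(fragments, tolerance = 10) {
  if (length(fragments) == 0L || all(is.na(fragments)))
    stop("no fragment evidence supplied")
  stopifnot(tolerance >= 0)
  fragments <- fragments[!is.na(fragments)]
  expected <- c(192, 380, 572)
  matched <- vapply(fragments, function(f) {
    d <- abs(expected - f)
    if (min(d) <= tolerance) expected[which.min(d)] else NA_real_
  }, numeric(1))
  if (anyNA(matched))
    stop("uncallable: band(s) at ",
         paste(fragments[is.na(matched)], collapse = ", "),
         " bp match no expected fragment within ", tolerance, " bp")
  pattern <- sort(unique(matched))
  pats <- .rflp_patterns()
  genotype <- NULL
  for (g in names(pats))
    if (identical(pattern, as.numeric(sort(pats[[g]])))) genotype <- g
  if (is.null(genotype))
    stop("uncallable: fragment pattern {",
         paste(pattern, collapse = ", "),
         "} matches none of CC/CT/TT")
  structure(list(genotype = genotype,
                 alleles = strsplit(genotype, "")[[1]],
                 evidence = data.frame(observed = fragments,
                                       matched = matched)),
            class = "gx_genotype_call")
}

#' @export
print.gx_genotype_call <- function(x, ...) {
  cat("RFLP genotype call:", x$genotype, "(",
      paste(x$evidence$matched, collapse = "+"), "bp )\n")
  invisible(x)
}

#' Vectorized genotype calling
#'
#' Applies [call_genotype()] to a list of fragment sets, returning `NA`
#' with a warning for uncallable subjects instead of failing.
#'
#' @param fragment_list List of numeric vectors, or a character vector of
#'   `";"`-separated lengths (the CSV serialization).
#' @param tolerance Matching tolerance in bp.
#' @return Character vector of genotypes (`NA` where uncallable).
#' @export
call_genotypes <- function(fragment_list, tolerance = 10) {
  if (is.character(fragment_list))
    fragment_list <- lapply(strsplit(fragment_list, ";"), as.numeric)
  out <- vapply(fragment_list, function(f) {
    tryCatch(call_genotype(f, tolerance)$genotype,
             error = function(e) NA_character_)
  }, character(1))
  if (anyNA(out))
    warning(sum(is.na(out)), " subject(s) uncallable", call. = FALSE)
  out
}

#' Cohort genotype and allele statistics
#'
#' Genotype counts and proportions, allele frequencies with
#' `f(T) = p(TT) + p(CT)/2`, and the minor allele frequency.
#'
#' @param genotypes Character vector of `CC`/`CT`/`TT` calls (`NA`
#'   dropped), or a named count vector.
#' @return List of class `gx_allele_stats` with `n`, `counts`,
#'   `proportions`, `f_C`, `f_T`, `maf`, `minor_allele`.
#' @export
genotype_frequencies <- function(genotypes) {
  if (is.numeric(genotypes)) {
    counts <- genotypes[c("CC", "CT", "TT")]
    counts[is.na(counts)] <- 0
  } else {
    genotypes <- genotypes[!is.na(genotypes)]
    validate_levels(genotypes, c("CC", "CT", "TT"), "genotype")
    counts <- table(factor(genotypes, levels = c("CC", "CT", "TT")))
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotype call required")
  props <- counts / n
  stats_ <- allele_frequencies(props)
  structure(c(list(n = n, counts = counts, proportions = props), stats_),
            class = "gx_allele_stats")
}

#' Allele frequencies from genotype proportions
#'
#' @param props Named proportions for `CC`, `CT`, `TT` (must sum to 1).
#' @return List with `f_C`, `f_T`, `maf` and `minor_allele`.
#' @export
allele_frequencies <- function(props) {
  props <- props[c("CC", "CT", "TT")]
  if (abs(sum(props) - 1) > 1e-6)
    stop("genotype proportions must sum to 1")
  f_T <- unname(props["TT"] + props["CT"] / 2)
  f_C <- 1 - f_T
  list(f_C = f_C, f_T = f_T, maf = min(f_C, f_T),
       minor_allele = if (f_T <= f_C) "T" else "C")
}

#' @export
print.gx_allele_stats <- function(x, ...) {
  cat("Genotypes (n =", x$n, "):",
      paste(sprintf("%s %.1f%%", names(x$proportions),
                    100 * x$proportions), collapse = ", "), "\n")
  cat(sprintf("Allele frequencies: f(C) = %.4f, f(T) = %.4f; MAF = %.4f (%s)\n",
              x$f_C, x$f_T, x$maf, x$minor_allele))
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: conditional on the observed allele counts, the
#' probability of every possible heterozygote count is computed (by the
#' standard recurrence over the conditional distribution) and the p-value
#' is the total probability of configurations no more likely than the
#' observed one. Included as a cohort QC aid.
#'
#' @param counts Named or positional counts for `CC`, `CT`, `TT` (the
#'   order is homozygote, heterozygote, homozygote).
#' @return List with `p_value`, `observed_het`, `n`.
#' @export
hwe_exact_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0),
            all(counts == round(counts)))
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_het <- counts[2]
  n_rare <- 2 * min(counts[1], counts[3]) + n_het
  # support of the heterozygote count given allele counts
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  hets <- hets[hets <= n_rare & (n_rare - hets) / 2 <= n &
                 (2 * n - n_rare - hets) / 2 >= 0]
  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_r(h) * n_c(h) / ((h+2)*(h+1))
  # where n_r, n_c are the rare/common homozygote counts at h
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    nr <- (n_rare - h) / 2
    nc <- n - nr - h
    logp[i] <- logp[i - 1] + log(4 * nr * nc) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  pval <- sum(p[p <= p[obs] * (1 + 1e-9)])
  list(p_value = min(1, pval), observed_het = n_het, n = n)
}
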