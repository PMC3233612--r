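#' Comparison configuration
#'
#' Bundles every tunable of the pairwise comparison machinery: the two
#' pham-membership thresholds, the protein scoring scheme, the nucleotide
#' scoring scheme used for whole-genome alignments, and the
#' Karlin-Altschul parameters used to turn raw alignment scores into
#' E-values.
#'
#' The defaults are the parameters chosen for routine database building:
#' a 32.5% identity threshold, a 1e-50 protein E-value threshold, and a
#' 1e-4 nucleotide E-value threshold. Protein alignments use BLOSUM62
#' with affine gap costs `gap_open + L * gap_extend` for a gap of length
#' `L` (11/1 by default). `karlin_lambda`/`karlin_K` default to the
#' published gapped BLOSUM62-11/1 values (0.267, 0.041). The nucleotide
#' lambda is solved numerically from the scoring scheme at uniform base
#' composition; `nt_K` defaults to the standard ungapped +1/-2 value.
#'
#' @param identity_threshold percent identity at or above which a protein
#'   pair is related (default 32.5).
#' @param evalue_threshold protein E-value at or below which a pair is
#'   related (default 1e-50).
#' @param nucleotide_evalue_threshold E-value cutoff for whole-genome
#'   nucleotide matches (default 1e-4).
#' @param protein_matrix substitution matrix name; must be a matrix
#'   object provided by Biostrings (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param nucleotide_match,nucleotide_mismatch nucleotide match/mismatch
#'   scores (+1/-2 by default).
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters for protein
#'   scores.
#' @param nt_K Karlin-Altschul K for the nucleotide scheme.
#' @return an object of class `comparison_config`.
#' @export
#' @examples
#' cfg <- comparison_config()
#' cfg$identity_threshold
comparison_config <- function(identity_threshold = 32.5,
                              evalue_threshold = 1e-50,
                              nucleotide_evalue_threshold = 1e-4,
                              protein_matrix = "BLOSUM62",
                              gap_open = 11,
                              gap_extend = 1,
                              nucleotide_match = 1,
                              nucleotide_mismatch = -2,
                              karlin_lambda = 0.267,
                              karlin_K = 0.041,
                              nt_K = 0.621) {
  stopifnot(is.numeric(identity_threshold), length(identity_threshold) == 1,
            identity_threshold > 0, identity_threshold <= 100)
  stopifnot(evalue_threshold > 0, nucleotide_evalue_threshold > 0)
  stopifnot(gap_open >= 0, gap_extend > 0)
  stopifnot(nucleotide_match > 0, nucleotide_mismatch < 0)
  stopifnot(karlin_lambda > 0, karlin_K > 0, nt_K > 0)
  cfg <- list(
    identity_threshold = identity_threshold,
    evalue_threshold = evalue_threshold,
    nucleotide_evalue_threshold = nucleotide_evalue_threshold,
    protein_matrix = protein_matrix,
    gap_open = gap_open,
    gap_extend = gap_extend,
    nucleotide_match = nucleotide_match,
    nucleotide_mismatch = nucleotide_mismatch,
    karlin_lambda = karlin_lambda,
    karlin_K = karlin_K,
    nt_lambda = nt_karlin_lambda(nucleotide_match, nucleotide_mismatch),
    nt_K = nt_K
  )
  class(cfg) <- "comparison_config"
  cfg
}

#' Ungapped Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for `lambda > 0` at
#' uniform base composition (p = 1/4), where `s_ij` is `match` on the
#' diagonal and `mismatch` off it. For +1/-2 this gives lambda of about
#' 1.3327 (natural-log units).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @return the positive root lambda.
#' @export
#' @examples
#' nt_karlin_lambda(1, -2)
nt_karlin_lambda <- function(match = 1, mismatch = -2) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) (4 * exp(l * match) + 12 * exp(l * mismatch)) / 16 - 1
  uniroot(f, c(1e-8, 10), tol = 1e-12)$root
}

#' @export
print.comparison_config <- function(x, ...) {
  cat("pham comparison configuration\n")
  cat(sprintf("  identity threshold: %.1f%%\n", x$identity_threshold))
  cat(sprintf("  protein E-value threshold: %g\n", x$evalue_threshold))
  cat(sprintf("  nucleotide E-value threshold: %g\n",
              x$nucleotide_evalue_threshold))
  cat(sprintf("  protein scoring: %s, gap %g/%g (lambda=%.3f, K=%.3f)\n",
              x$protein_matrix, x$gap_open, x$gap_extend,
              x$karlin_lambda, x$karlin_K))
  cat(sprintf("  nucleotide scoring: %+g/%+g (lambda=%.4f, K=%.3f)\n",
              x$nucleotide_match, x$nucleotide_mismatch,
              x$nt_lambda, x$nt_K))
  invisible(x)
}

# Protein alphabet accepted everywhere: the 20 standard residues plus X.
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","X")

# Cache the scoring matrix lookup (Biostrings ships BLOSUM/PAM matrices).
.pham_env <- new.env(parent = emptyenv())

protein_submatrix <- function(config) {
  key <- config$protein_matrix
  if (!is.null(.pham_env[[key]])) return(.pham_env[[key]])
  mat <- tryCatch(
    getExportedValue("Biostrings", key),
    error = function(e) {
      e2 <- new.env()
      utils::data(list = key, package = "Biostrings", envir = e2)
      get(key, envir = e2)
    }
  )
  missing <- setdiff(AA_ALPHABET, rownames(mat))
  if (length(missing) > 0)
    stop("substitution matrix ", key, " lacks letters: ",
         paste(missing, collapse = ","))
  mat <- mat[AA_ALPHABET, AA_ALPHABET]
  storage.mode(mat) <- "double"
  .pham_env[[key]] <- mat
  mat
}

# Encode a protein string as 1-based indices into AA_ALPHABET; errors on
# any letter outside the 20 standard residues + X.
encode_protein <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx))
    stop("protein sequence contains invalid letter(s): ",
         paste(unique(ch[is.na(idx)]), collapse = ","))
  idx
}
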