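# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Percentages in summary output are rounded half-away-from-zero to a fixed
#' number of decimals (so 34.6095 -> 34.6, 33.333 -> 33.3), unlike base
#' [round()]'s round-half-to-even.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Controlled vocabularies -----------------------------------------------------

yome_categories <- function() c("yome", "well_annotated", "insufficient", "excluded")
final_categories <- function() c("yome", "well_annotated", "excluded")

yome_kbs <- function() c("ecocyc", "ecogene", "uniprot", "regulondb", "refseq")

yome_feature_types <- function() {
  c("description", "summary", "evidence", "annotation_score",
    "reaction_equation", "complex", "tf_evidence", "pseudogene_flag",
    "phantom_flag", "insertion_flag", "domain_only", "other")
}

# Category precedence within one knowledge base: a definite negative signal
# (excluded) beats positive evidence, which beats a low-annotation signal.
category_rank <- function() c(yome = 1L, well_annotated = 2L, excluded = 3L)

# Circular geometry ------------------------------------------------------------

# shortest angular distance on the circle, elementwise
circ_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution;
# used by the synthetic position generator. kappa = 0 falls back to uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- theta %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# IO helpers -------------------------------------------------------------------

read_tsv_chr <- function(path) {
  utils::read.delim(path, colClasses = "character", sep = "\t",
                    quote = "", check.names = FALSE, na.strings = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

stop_missing_file <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  invisible(path)
}
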