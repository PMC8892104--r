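#' @keywords internal
"_PACKAGE"

# Compartments of the intestinal design, in anatomical order.
GUT_COMPARTMENTS <- c("duodenum", "jejunum", "ileum", "ceca")

# Lines of the divergently selected broiler population.
GUT_LINES <- c("lean", "fat")

#' Derive a reproducible substream seed from a master seed
#'
#' All layers of the simulator draw from named substreams of one master seed
#' so a layer can be regenerated independently without disturbing the others.
#'
#' @param master integer master seed.
#' @param stream character name of the substream (e.g. `"phenotypes"`).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(master) * 2654435 + h) %% 2147483647L)
}

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Two-sample t statistic shared by the Metastats stage and the phenotype
# utility. Welch form by default; pooled variance available for the
# Table-1-style trait comparisons.
t_statistic <- function(x, y, pooled = FALSE) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (pooled) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
  }
  (mx - my) / se
}

#' Pooled-variance two-sample t test for phenotype comparisons
#'
#' Thin utility for line comparisons of phenotype tables (Student's t with
#' pooled variance), sharing its statistic code with the permutation stage.
#'
#' @param x,y numeric vectors for the two groups.
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
line_t_test <- function(x, y) {
  t <- t_statistic(x, y, pooled = TRUE)
  df <- length(x) + length(y) - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Validate that a design data frame has the expected columns and invariants.
check_design <- function(design) {
  need <- c("sample_id", "bird_id", "line", "compartment")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("sample_ids must be unique")
  if (length(unique(design$line)) < 2) stop("both lines must be non-empty")
  invisible(design)
}
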