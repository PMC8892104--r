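# Synthetic phenotype and design generator.
#
# Emulates the two-line broiler design: n birds per line, each measured for
# body weight (BW, kg), abdominal fat weight (AFW, g), abdominal fat
# percentage (AFP = 100 * AFW / (1000 * BW)) and 13 serum biochemical
# indices plus two derived ratios. Line means/SDs default to the study
# population's values; a configurable subset of serum traits is coupled to
# adiposity through a shared latent bird-level factor, so the abdominal-fat
# relevant trait (AFRT) screen has planted positives to recover.

#' Default per-trait phenotype parameters
#'
#' One row per simulated trait with per-line means and SDs (SD = reported
#' SE * sqrt(10), the study's per-line sample size) and `afp_cor`, the
#' within-line target correlation of the trait with the latent adiposity
#' factor that drives AFW. Traits with `afp_cor != 0` are the planted
#' AFRT positives; their signs follow the direction of the line effect.
#' `HDL_C_LDL_C` and `AST_ALT` are derived ratios, not sampled directly.
#'
#' @return A data.frame with columns `trait`, `lean_mean`, `lean_sd`,
#'   `fat_mean`, `fat_sd`, `afp_cor`.
#' @export
phenotype_params <- function() {
  p <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
trait   lean_mean lean_se fat_mean fat_se afp_cor
BW        2.218   0.015    2.189   0.129  0
AFW      14.319   1.127  117.869   4.306  1
TG        0.322   0.023    0.378   0.029  0
CHO       3.051   0.091    3.271   0.111  0.8
HDL_C     2.164   0.071    2.573   0.094  0.8
LDL_C     0.649   0.036    0.591   0.039 -0.3
TBA       2.743   0.484    2.943   0.610  0
TP       29.607   0.653   36.657   1.369  0.8
ALB      13.143   0.310   15.157   0.494  0.8
GLU      12.174   0.132   10.761   0.225 -0.8
AST     288.786  12.894  265.000  13.903  0
ALT       2.500   0.272    2.286   0.194  0
CREA      3.157   0.329    3.750   0.379  0
GGT      14.357   0.862   19.071   0.863  0.8
UA      162.743  17.384  284.350  39.886  0.8
")
  p$lean_sd <- p$lean_se * sqrt(10)
  p$fat_sd <- p$fat_se * sqrt(10)
  p[, c("trait", "lean_mean", "lean_sd", "fat_mean", "fat_sd", "afp_cor")]
}

#' Generate a phenotype table and sample design
#'
#' Draws one row per bird. Within each line, standardized trait deviates
#' follow a one-factor model `z_t = c_t * f + sqrt(1 - c_t^2) * e_t`, where
#' `f` is the bird's latent adiposity factor (`c_AFW = 1`, so AFW is the
#' anchor) and `c_t` is the trait's `afp_cor`. AFP is computed from the
#' sampled AFW and BW, never drawn. Alternatively `params$cor_matrix` may
#' supply a full trait correlation matrix; a non-positive-semi-definite
#' request is replaced by the nearest valid correlation matrix with a note.
#'
#' @param n_per_line birds per line (>= 3).
#' @param params data.frame as [phenotype_params()], optionally with an
#'   attached `cor_matrix` attribute (traits x traits).
#' @param seed integer seed.
#' @return A list with `phenotypes` (one row per bird; includes derived
#'   `AFP`, `HDL_C_LDL_C`, `AST_ALT`), `design` (one row per
#'   bird-compartment sample), `latent` (bird-level adiposity factor) and
#'   `truth` (planted trait couplings and line effects).
#' @export
generate_phenotypes <- function(n_per_line = 10, params = phenotype_params(),
                                seed = 1) {
  stopifnot(n_per_line >= 3)
  if (any(params$lean_sd <= 0) || any(params$fat_sd <= 0)) {
    stop("trait SDs must be positive")
  }
  if (any(abs(params$afp_cor) > 1)) {
    stop("correlation entries must lie in [-1, 1]")
  }
  traits <- params$trait
  nt <- length(traits)
  cm <- attr(params, "cor_matrix")
  if (!is.null(cm)) {
    if (any(abs(cm) > 1)) stop("correlation entries must lie in [-1, 1]")
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      message("requested correlation matrix is not positive semi-definite; ",
              "using nearest valid correlation matrix")
      cm <- as.matrix(Matrix::nearPD(cm, corr = TRUE)$mat)
    }
    R <- chol(cm + diag(1e-10, nt))
  }

  with_seed(seed, {
    per_line <- lapply(GUT_LINES, function(ln) {
      mu <- if (ln == "lean") params$lean_mean else params$fat_mean
      sd <- if (ln == "lean") params$lean_sd else params$fat_sd
      if (is.null(cm)) {
        f <- stats::rnorm(n_per_line)
        e <- matrix(stats::rnorm(n_per_line * nt), n_per_line, nt)
        cc <- params$afp_cor
        cc[traits == "AFW"] <- 1
        z <- sweep(e, 2, sqrt(1 - cc^2), `*`) +
          outer(f, cc)
      } else {
        z <- matrix(stats::rnorm(n_per_line * nt), n_per_line, nt) %*% R
        f <- z[, which(traits == "AFW")]
      }
      vals <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
      colnames(vals) <- traits
      vals[, "AFW"] <- pmax(vals[, "AFW"], 0)
      list(values = vals, latent = f)
    })
    names(per_line) <- GUT_LINES

    bird_id <- c(sprintf("L%02d", seq_len(n_per_line)),
                 sprintf("F%02d", seq_len(n_per_line)))
    line <- rep(GUT_LINES, each = n_per_line)
    vals <- rbind(per_line$lean$values, per_line$fat$values)
    phen <- data.frame(bird_id = bird_id, line = line, vals,
                       stringsAsFactors = FALSE, row.names = NULL)
    phen$AFP <- 100 * phen$AFW / (1000 * phen$BW)
    phen$HDL_C_LDL_C <- phen$HDL_C / phen$LDL_C
    phen$AST_ALT <- phen$AST / phen$ALT

    design <- expand.grid(bird_id = bird_id, compartment = GUT_COMPARTMENTS,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design$line <- phen$line[match(design$bird_id, phen$bird_id)]
    design$sample_id <- paste(design$bird_id, design$compartment, sep = "_")
    design <- design[order(match(design$compartment, GUT_COMPARTMENTS),
                           design$bird_id),
                     c("sample_id", "bird_id", "line", "compartment")]
    rownames(design) <- NULL

    latent <- data.frame(bird_id = bird_id, line = line,
                         adiposity = c(per_line$lean$latent,
                                       per_line$fat$latent))
    truth <- list(
      # strongly coupled serum traits are the planted AFRT positives;
      # weak couplings (|r| < 0.5, e.g. LDL-C shaping the HDL/LDL ratio)
      # are not counted as planted
      trait_correlated = params[abs(params$afp_cor) >= 0.5 &
                                  params$trait != "AFW",
                                c("trait", "afp_cor")],
      line_differential = params$trait[abs(params$lean_mean -
                                             params$fat_mean) >
                                         (params$lean_sd + params$fat_sd) / 2],
      seed = seed
    )
    list(phenotypes = phen, design = design, latent = latent, truth = truth)
  })
}

# Standardized AFP across all birds: the cross-line adiposity covariate the
# microbiome and expression layers couple to.
afp_zscore <- function(phenotypes) {
  z <- as.numeric(scale(phenotypes$AFP))
  names(z) <- phenotypes$bird_id
  z
}
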