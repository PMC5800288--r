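# Strain-panel generator: molecular measurements (piRNA RPM, P and KP
# mRNA, cluster-read fraction) and gonadal-dysgenesis scores generated from
# a logistic model in which piRNA and KP levels act as suppressors.

#' Simulate a strain panel with GD phenotypes
#'
#' Predictors are drawn from lognormal distributions; GD percentages follow
#' GD = 100 * logistic(intercept + beta_pirna * z(piRNA) + beta_kp * z(KP)
#' + e), e ~ N(0, noise_sd), clamped to [0, 100] (the logistic link already
#' guarantees the range). Negative betas encode suppression of dysgenesis.
#' F2 scores use a dampened linear predictor (partial recovery across
#' generations); cross-A* (susceptibility) scores depend on the maternal
#' piRNA level only. True coefficients and linear predictors are recorded.
#'
#' @param n_strains Number of strains (>= 4).
#' @param beta_pirna,beta_kp Generative coefficients on the z-scored
#'   predictors (defaults -3 and -1: both suppressors).
#' @param noise_sd Gaussian noise on the linear predictor (default 0.5,
#'   moderate relative to the default effect sizes).
#' @param intercept Linear-predictor intercept (default 0).
#' @param f2_damping Multiplier on the linear predictor for F2 (default 0.5).
#' @param seed Integer seed.
#' @return List of class \code{strain_panel}: \code{panel} data.frame
#'   (strain, pirna_rpm, p_mrna, kp_mrna, cluster_read_pct, gd_f1, gd_f2,
#'   gd_astar, inducibility, susceptibility) and \code{truth} (betas,
#'   z-scores, linear predictors, seed).
#' @export
simulate_strain_panel <- function(n_strains = 5L, beta_pirna = -3, beta_kp = -1,
                                  noise_sd = 0.5, intercept = 0,
                                  f2_damping = 0.5, seed = 1L) {
  n_strains <- as.integer(n_strains)
  stopifnot(n_strains >= 4L, noise_sd >= 0)

  with_seed(seed, {
    pirna <- stats::rlnorm(n_strains, meanlog = log(1000), sdlog = 1)
    kp <- stats::rlnorm(n_strains, meanlog = log(2), sdlog = 0.8)
    p_mrna <- stats::rlnorm(n_strains, meanlog = log(1), sdlog = 0.6)
    cluster_pct <- round(stats::runif(n_strains, 0, 60), 1)

    z <- function(v) if (stats::sd(v) == 0) v * 0 else (v - mean(v)) / stats::sd(v)
    zp <- z(pirna); zk <- z(kp)
    lin <- intercept + beta_pirna * zp + beta_kp * zk
    gd_f1 <- 100 * stats::plogis(lin + stats::rnorm(n_strains, 0, noise_sd))
    gd_f2 <- 100 * stats::plogis(f2_damping * lin + stats::rnorm(n_strains, 0, noise_sd))
    gd_astar <- 100 * stats::plogis(intercept + beta_pirna * zp +
                                      stats::rnorm(n_strains, 0, noise_sd))
  })
  gd_f1 <- pmin(100, pmax(0, gd_f1))
  gd_f2 <- pmin(100, pmax(0, gd_f2))
  gd_astar <- pmin(100, pmax(0, gd_astar))

  panel <- data.frame(
    strain = sprintf("L%02d", seq_len(n_strains)),
    pirna_rpm = pirna, p_mrna = p_mrna, kp_mrna = kp,
    cluster_read_pct = cluster_pct,
    gd_f1 = gd_f1, gd_f2 = gd_f2, gd_astar = gd_astar,
    stringsAsFactors = FALSE
  )
  panel$inducibility <- as.character(label_phenotype(panel$gd_f1, "A"))
  panel$susceptibility <- as.character(label_phenotype(panel$gd_astar, "A*"))

  structure(list(
    panel = panel,
    truth = list(beta_pirna = beta_pirna, beta_kp = beta_kp,
                 noise_sd = noise_sd, intercept = intercept,
                 z_pirna = zp, z_kp = zk, linear_predictor = lin, seed = seed)
  ), class = "strain_panel")
}

#' Write / read a strain panel as TSV
#'
#' Header: strain, pirna_rpm, p_mrna, kp_mrna, cluster_read_pct, gd_f1,
#' gd_f2, gd_astar, inducibility, susceptibility.
#'
#' @param panel A \code{strain_panel} or its panel data.frame.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_panel_tsv <- function(panel, path) {
  if (inherits(panel, "strain_panel")) panel <- panel$panel
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Association analysis of a strain panel
#'
#' The panel-level statistics reported in this workflow: Pearson
#' correlations of GD with each molecular measurement, a multiple
#' regression of F1 GD on piRNA RPM and KP mRNA, furthest-neighbor
#' clustering of strains over the molecular features, and phenotype labels.
#'
#' @param panel A \code{strain_panel} or panel data.frame.
#' @param predictors Columns used in the regression (default piRNA RPM and
#'   KP mRNA).
#' @param features Columns used for clustering (default the four molecular
#'   measurements).
#' @return List: \code{correlations} data.frame, \code{regression}
#'   (\code{regression_result}), \code{dendrogram} (hclust), \code{newick},
#'   \code{labels} data.frame.
#' @export
associate_panel <- function(panel,
                            predictors = c("pirna_rpm", "kp_mrna"),
                            features = c("pirna_rpm", "p_mrna", "kp_mrna",
                                         "cluster_read_pct")) {
  if (inherits(panel, "strain_panel")) panel <- panel$panel
  stopifnot(all(c(predictors, features, "gd_f1") %in% names(panel)))

  cors <- do.call(rbind, lapply(features, function(v) {
    pr <- pearson(panel[[v]], panel$gd_f1)
    data.frame(variable = v, r = pr$r, p = pr$p, n = pr$n,
               stringsAsFactors = FALSE)
  }))

  reg <- multiple_regression(panel$gd_f1, panel[, predictors, drop = FALSE])
  hc <- hcluster(panel[, features, drop = FALSE], labels = panel$strain)

  list(correlations = cors,
       regression = reg,
       dendrogram = hc,
       newick = dendrogram_newick(hc),
       labels = data.frame(strain = panel$strain,
                           inducibility = as.character(label_phenotype(panel$gd_f1, "A")),
                           susceptibility = as.character(label_phenotype(panel$gd_astar, "A*")),
                           stringsAsFactors = FALSE))
}
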