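# Linear repression model: ordinary least squares on the feature set,
# prediction of log2 fold-change (more negative = stronger repression),
# pair-level aggregation of site features, and the oriented empirical
# percentile transform.

#' The registered feature names
#' @export
feature_registry <- function() {
  c("dg_duplex", "dg_binding", "dg_seed_duplex", "dg_seed_binding",
    "dg_open", "dg_total", "pover_binomial", "pover_exact",
    "au_content", "utr_position", "three_prime_pairing",
    "bls", "phylop_score", "n_sites", "mirmap_score")
}

#' Default repression directions of the features
#'
#' `lower_is_stronger`: all free energies, both over-representation
#' probabilities, UTR position and the predicted score itself (more
#' negative log2 fold-change = stronger repression). `higher_is_stronger`:
#' branch length score, phyloP score, AU content, 3' pairing and site
#' count.
#'
#' @return named character vector over the registry.
#' @export
default_directions <- function() {
  lower <- c("dg_duplex", "dg_binding", "dg_seed_duplex", "dg_seed_binding",
             "dg_open", "dg_total", "pover_binomial", "pover_exact",
             "utr_position", "mirmap_score")
  higher <- c("bls", "phylop_score", "au_content", "three_prime_pairing",
              "n_sites")
  stats::setNames(
    ifelse(feature_registry() %in% lower,
           "lower_is_stronger", "higher_is_stronger"),
    feature_registry())[c(lower, higher)][feature_registry()]
}

# features summed over sites when aggregating to the pair level
PAIR_SUM_FEATURES <- c("dg_duplex", "dg_binding", "dg_seed_duplex",
                       "dg_seed_binding", "dg_open", "dg_total",
                       "au_content", "utr_position", "three_prime_pairing",
                       "bls", "phylop_score")

#' Aggregate site-level features to the pair level
#'
#' Energy, context and conservation features are summed over the sites of
#' the pair; the site count is recorded as `n_sites`. Over-representation
#' features are pair-level quantities (functions of the total match count)
#' and must be supplied by the caller. Features missing (NA) at some sites
#' are summed over the available sites and their names recorded in the
#' `missing` attribute.
#'
#' @param site_features data.frame, one row per site, feature columns.
#' @return named numeric vector of pair-level features with attribute
#'   `missing`.
#' @export
aggregate_pair <- function(site_features) {
  if (is.null(nrow(site_features)) || nrow(site_features) == 0) {
    stop("aggregate_pair needs at least one site")
  }
  feats <- intersect(PAIR_SUM_FEATURES, names(site_features))
  out <- vapply(feats, function(f) {
    v <- site_features[[f]]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }, numeric(1))
  missing <- feats[vapply(feats, function(f) anyNA(site_features[[f]]),
                          logical(1))]
  out <- c(out, n_sites = nrow(site_features))
  attr(out, "missing") <- missing
  out
}

#' Fit the linear repression model
#'
#' Ordinary least squares of the response (log2 fold-change) on the
#' feature columns with an intercept. Rank deficiency is a hard error
#' naming the collinear features.
#'
#' @param features data.frame or matrix, pairs x features, no NA.
#' @param response numeric log2 fold-change vector.
#' @return a `mirmap_model`: list with `intercept`, `coefficients` (named),
#'   `training_r2`, `fitted`, `residuals`.
#' @export
fit_linear_model <- function(features, response) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(response)) stop("features and response must have no NA")
  if (nrow(X) < ncol(X) + 1) stop("need more rows than features")
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xi)
  if (qr_$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_$pivot[(qr_$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; collinear features: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(Xi, response)
  rss <- sum(fit$residuals^2)
  tss <- sum((response - mean(response))^2)
  structure(list(intercept = unname(fit$coefficients[1]),
                 coefficients = fit$coefficients[-1],
                 training_r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 fitted = fit$fitted.values,
                 residuals = fit$residuals),
            class = "mirmap_model")
}

#' Predict repression from features
#'
#' `intercept + sum(coefficient * value)`; more negative = stronger
#' predicted repression. Missing model features are a hard error.
#'
#' @param model a `mirmap_model`.
#' @param features named numeric vector or data.frame of feature values.
#' @return predicted log2 fold-change (vector for data.frame input).
#' @export
predict_repression <- function(model, features) {
  need <- names(model$coefficients)
  if (is.data.frame(features)) {
    miss <- setdiff(need, names(features))
    if (length(miss) > 0) {
      stop("missing features: ", paste(miss, collapse = ", "))
    }
    X <- as.matrix(features[need])
    drop(model$intercept + X %*% model$coefficients)
  } else {
    miss <- setdiff(need, names(features))
    if (length(miss) > 0) {
      stop("missing features: ", paste(miss, collapse = ", "))
    }
    unname(model$intercept + sum(model$coefficients * features[need]))
  }
}

#' Oriented empirical percentile of a feature value
#'
#' Ranks the value within the background sample, oriented by the feature's
#' repression direction so that 100 is the strongest predicted repression
#' and 0 the weakest; ties get averaged ranks.
#'
#' @param value the raw feature value (vectorized).
#' @param background numeric background sample for the feature.
#' @param feature feature name (looked up in `directions`).
#' @param directions named direction map; see [default_directions()].
#' @return percentile(s) in `[0, 100]`.
#' @export
percentile_transform <- function(value, background, feature,
                                 directions = default_directions()) {
  if (length(background) == 0) stop("background sample is empty")
  dir <- directions[feature]
  if (is.na(dir)) stop("feature '", feature, "' absent from direction map")
  s_bg <- if (dir == "lower_is_stronger") -background else background
  s_val <- if (dir == "lower_is_stronger") -value else value
  n <- length(s_bg)
  vapply(s_val, function(s) {
    if (n == 1) return(50)
    weaker <- sum(s_bg < s)
    ties <- sum(s_bg == s)
    r <- weaker + (ties + 1) / 2
    min(100, max(0, 100 * (r - 1) / (n - 1)))
  }, numeric(1))
}

#' Demo linear model with synthetic coefficients
#'
#' Coefficients calibrated on this package's synthetic repression
#' generator, shipped so the scoring pipeline runs out of the box. They are
#' synthetic demonstration values, not a published model; refit with
#' [fit_linear_model()] on real training data for production use.
#'
#' @return a `mirmap_model`.
#' @export
demo_model <- function() {
  structure(list(
    intercept = -0.05,
    coefficients = c(dg_duplex = 0.004, dg_binding = 0.003,
                     dg_seed_duplex = 0.004, dg_seed_binding = 0.003,
                     dg_open = 0.008, dg_total = 0.006,
                     pover_binomial = 0.15, pover_exact = 0.20,
                     au_content = -0.30, utr_position = 1e-4,
                     three_prime_pairing = -0.02,
                     n_sites = -0.08),
    training_r2 = NA_real_,
    fitted = NULL, residuals = NULL), class = "mirmap_model")
}

#' Serialize / deserialize a linear model
#'
#' Flat key=value text: `intercept`, `training_r2`, `registry_version` and
#' one `coef.<feature>` line per coefficient.
#'
#' @param model a `mirmap_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  lines <- c(sprintf("registry_version=1"),
             sprintf("intercept=%.17g", model$intercept),
             sprintf("training_r2=%.17g",
                     if (is.na(model$training_r2)) NA else model$training_r2),
             sprintf("coef.%s=%.17g", names(model$coefficients),
                     model$coefficients))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  co <- grepl("^coef\\.", keys)
  structure(list(
    intercept = as.numeric(vals[keys == "intercept"]),
    coefficients = stats::setNames(as.numeric(vals[co]),
                                   sub("^coef\\.", "", keys[co])),
    training_r2 = suppressWarnings(as.numeric(vals[keys == "training_r2"])),
    fitted = NULL, residuals = NULL), class = "mirmap_model")
}
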