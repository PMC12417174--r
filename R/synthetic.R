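#' Specification of a synthetic clinical-style tabular dataset
#'
#' Describes the statistical structure the pipeline assumes: a subset of
#' informative features whose class-conditional means are separated by
#' `effect_size` noise standard deviations, label-independent noise features,
#' configurable class imbalance, optional zero-coded missingness imposed after
#' rescaling into strictly positive feature ranges (so the 0 code is
#' out-of-support and unambiguous), and an optional polynomial link between
#' two features for exercising the regression imputer.
#'
#' @param n_samples number of rows.
#' @param n_features number of features.
#' @param informative integer indices (1-based) of the informative features.
#' @param effect_size class-mean separation in noise-SD units.
#' @param n_classes 2 or 3.
#' @param class_priors probability vector of length `n_classes`; must sum
#'   to 1.
#' @param missing_spec named list mapping feature name to missing fraction in
#'   \[0, 1).
#' @param feature_ranges two-column matrix (low, high) per feature, or a
#'   single (low, high) pair recycled; lows must be > 0 when missingness is
#'   requested. Default c(50, 200), a generic clinical measurement range.
#' @param polynomial_link optional list
#'   `list(target =, source =, coef = c(b0, b1, b2, ...), noise_sd =)`
#'   making feature `target` a polynomial in feature `source` plus Gaussian
#'   noise (applied before rescaling).
#' @param feature_names optional character vector of length `n_features`.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_features, informative = integer(),
                           effect_size = 1.5, n_classes = 2L,
                           class_priors = rep(1 / n_classes, n_classes),
                           missing_spec = list(),
                           feature_ranges = c(50, 200),
                           polynomial_link = NULL,
                           feature_names = NULL) {
  stopifnot(n_samples >= 1L, n_features >= 1L,
            all(informative >= 1L), all(informative <= n_features),
            n_classes %in% c(2L, 3L),
            length(class_priors) == n_classes,
            abs(sum(class_priors) - 1) < 1e-9,
            all(unlist(missing_spec) >= 0), all(unlist(missing_spec) < 1))
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(n_features))
  stopifnot(length(feature_names) == n_features)
  if (!is.matrix(feature_ranges))
    feature_ranges <- matrix(feature_ranges, n_features, 2, byrow = TRUE)
  stopifnot(nrow(feature_ranges) == n_features,
            all(feature_ranges[, 1] < feature_ranges[, 2]))
  if (length(missing_spec) && any(feature_ranges[, 1] <= 0))
    stop_named("skipgru_bad_spec",
               "missingness requires strictly positive feature ranges")
  bad <- setdiff(names(missing_spec), feature_names)
  if (length(bad))
    stop_named("skipgru_bad_spec", "missing_spec names not in features: %s",
               paste(bad, collapse = ", "))
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 informative = as.integer(informative),
                 effect_size = effect_size,
                 n_classes = as.integer(n_classes),
                 class_priors = class_priors,
                 missing_spec = missing_spec,
                 feature_ranges = feature_ranges,
                 polynomial_link = polynomial_link,
                 feature_names = feature_names),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset from a specification
#'
#' Labels are drawn from the class priors; informative features from
#' class-conditional unit-variance Gaussians with class `c` centred at
#' `c * effect_size`; noise features from a class-independent standard
#' Gaussian. The optional polynomial link then overwrites its target feature;
#' all features are affinely mapped into their `feature_ranges`; finally,
#' missingness is imposed by zeroing a random subset of entries per column.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the draw is fully reproducible from it.
#' @return list with `dataset` (a [tabular_dataset()] whose `missing_columns`
#'   are the names in `spec$missing_spec`) and `truth` (ground-truth record:
#'   informative indices, link description, the pre-missingness feature
#'   matrix, and the seed).
#' @export
generate_synthetic <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    n <- spec$n_samples
    d <- spec$n_features
    labels <- sample.int(spec$n_classes, n, replace = TRUE,
                         prob = spec$class_priors) - 1L
    X <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(NULL, spec$feature_names))
    for (j in spec$informative)
      X[, j] <- X[, j] + labels * spec$effect_size
    link <- spec$polynomial_link
    if (!is.null(link)) {
      src <- X[, link$source]
      mu <- drop(poly_basis(cbind(src), length(link$coef) - 1L) %*%
                   link$coef[-1L]) + link$coef[1L]
      X[, link$target] <- mu + stats::rnorm(n, sd = link$noise_sd %||% 1)
    }
    # affine map into the requested ranges (z in [-3,3] covers ~99.7%; clip)
    for (j in seq_len(d)) {
      lo <- spec$feature_ranges[j, 1]; hi <- spec$feature_ranges[j, 2]
      z <- pmin(3, pmax(-3, X[, j]))
      X[, j] <- lo + (z + 3) / 6 * (hi - lo)
    }
    complete <- X
    for (f in names(spec$missing_spec)) {
      frac <- spec$missing_spec[[f]]
      if (frac > 0) {
        idx <- sample.int(n, size = round(frac * n))
        X[idx, f] <- 0
      }
    }
    class_names <- c("class0", "class1", "class2")[seq_len(spec$n_classes)]
    ds <- tabular_dataset(X, labels, class_names,
                          missing_columns = names(spec$missing_spec))
    list(dataset = ds,
         truth = list(informative = spec$informative,
                      effect_size = spec$effect_size,
                      polynomial_link = link,
                      complete_features = complete,
                      seed = as.integer(seed)))
  })
}

#' Named catalog of synthetic-dataset presets
#'
#' `pima-like` mirrors the published PIMA Indian diabetes layout: 768 rows,
#' 8 clinical features, two classes with 500 non-diabetic and 268 diabetic
#' patients, zero-coded missingness in glucose, blood pressure, skin
#' thickness, insulin and BMI at fractions typical of the real table, and the
#' clinically selected features planted as informative. `lmch-like` mirrors
#' the LMCH laboratory layout: 1000 rows, 12 features, three classes with
#' priors proportional to 103 normal / 53 prediabetes / 844 diabetes.
#'
#' @return named list of [synthetic_spec()] objects.
#' @export
synthetic_presets <- function() {
  pima_names <- c("pregnancies", "glucose", "blood_pressure",
                  "skin_thickness", "insulin", "bmi",
                  "pedigree_function", "age")
  pima <- synthetic_spec(
    n_samples = 768L, n_features = 8L,
    informative = match(c("glucose", "insulin", "bmi",
                          "pedigree_function", "age"), pima_names),
    effect_size = 1.5, n_classes = 2L,
    class_priors = c(500, 268) / 768,
    missing_spec = list(glucose = 0.01, blood_pressure = 0.05,
                        skin_thickness = 0.30, insulin = 0.45, bmi = 0.01),
    feature_ranges = matrix(c(1, 17,    # pregnancies
                              44, 199,  # glucose
                              24, 122,  # blood pressure
                              7, 99,    # skin thickness
                              14, 846,  # insulin
                              18, 67,   # bmi
                              0.08, 2.4,# pedigree function
                              21, 81),  # age
                            8, 2, byrow = TRUE),
    feature_names = pima_names)
  lmch_names <- c("age", "gender", "blood_sugar", "urea", "bmi",
                  "creatinine_ratio", "cholesterol", "triglycerides",
                  "hdl", "ldl", "vldl", "hba1c")
  lmch <- synthetic_spec(
    n_samples = 1000L, n_features = 12L,
    informative = match(c("hba1c", "blood_sugar", "bmi", "age", "ldl"),
                        lmch_names),
    effect_size = 1.5, n_classes = 3L,
    class_priors = c(103, 53, 844) / 1000,
    feature_ranges = matrix(c(20, 79, 0, 1, 60, 500, 0.5, 39, 19, 48,
                              6, 800, 0.1, 10, 0.3, 14, 0.2, 10, 0.3, 10,
                              0.1, 35, 0.9, 16),
                            12, 2, byrow = TRUE),
    feature_names = lmch_names)
  list(`pima-like` = pima, `lmch-like` = lmch)
}
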