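#' Construct a logistic model specification
#'
#' A `model_spec` stores a published (or updated) logistic prediction model as
#' data: one intercept on the log-odds scale plus a table of coded predictor
#' terms. Scoring a cohort with [linear_predictor()] reproduces the model's
#' prognostic index (weighted sum of coded covariates); [score_cohort()] adds
#' the corresponding predicted risks.
#'
#' Supported term codings:
#' * `binary` — 0/1 (or logical) indicator;
#' * `count` — nonnegative integer, coefficient applies per unit;
#' * `categorical` — indicator for `level` within a declared level set
#'   `levels`; the `reference` level carries an implicit coefficient of 0;
#' * `continuous` — coded value is `(x / scale)^degree`, so linear plus
#'   quadratic codings of one predictor are two rows sharing the same `scale`.
#'
#' @param name Short machine name (used by [write_model_spec()] round-trips).
#' @param label Human-readable description.
#' @param outcome Name of the binary outcome column the model predicts.
#' @param intercept Model intercept on the log-odds scale.
#' @param terms Data frame with columns `predictor`, `type`, and per type:
#'   `level`, `reference`, `levels` (list-column of character vectors),
#'   `scale`, `degree`, and one of `coefficient` (log-odds) or `odds_ratio`.
#' @param notes Optional character vector of caveats carried with the spec.
#' @param provenance Optional list describing how the spec was produced
#'   (filled in by [recalibrate()] and [refit()]).
#'
#' @return An object of class `model_spec`.
#' @seealso [load_model()], [linear_predictor()], [score_cohort()],
#'   [tidy.model_spec()]
#' @export
model_spec <- function(name, label = name, outcome, intercept, terms,
                       notes = character(), provenance = NULL) {
  terms <- tibble::as_tibble(terms)
  if (!"coefficient" %in% names(terms)) terms$coefficient <- NA_real_
  if (!"odds_ratio" %in% names(terms)) terms$odds_ratio <- NA_real_
  fill <- is.na(terms$coefficient)
  terms$coefficient[fill] <- log(terms$odds_ratio[fill])
  terms$odds_ratio[is.na(terms$odds_ratio)] <-
    exp(terms$coefficient[is.na(terms$odds_ratio)])
  for (col in c("level", "reference")) {
    if (!col %in% names(terms)) terms[[col]] <- NA_character_
  }
  if (!"levels" %in% names(terms)) terms$levels <- list(NULL)
  if (!"scale" %in% names(terms)) terms$scale <- NA_real_
  terms$scale[is.na(terms$scale)] <- 1
  if (!"degree" %in% names(terms)) terms$degree <- NA_real_
  terms$degree[is.na(terms$degree)] <- 1
  terms <- terms[, c("predictor", "type", "level", "reference", "levels",
                     "scale", "degree", "coefficient", "odds_ratio")]
  out <- structure(
    list(name = name, label = label, outcome = outcome,
         intercept = as.numeric(intercept), terms = terms,
         notes = notes, provenance = provenance),
    class = "model_spec"
  )
  validate_model_spec(out)
}

validate_model_spec <- function(x) {
  stopifnot(inherits(x, "model_spec"))
  if (length(x$intercept) != 1L || !is.finite(x$intercept)) {
    abort("`model_spec` must carry exactly one finite intercept.")
  }
  tm <- x$terms
  if (!all(is.finite(tm$coefficient))) {
    abort("All term coefficients must be finite.")
  }
  bad <- setdiff(unique(tm$type),
                 c("binary", "count", "categorical", "continuous"))
  if (length(bad)) {
    abort(paste0("Unknown term coding(s): ", paste(bad, collapse = ", "), "."))
  }
  cat_rows <- tm$type == "categorical"
  if (any(cat_rows)) {
    ok <- !is.na(tm$level[cat_rows]) & !is.na(tm$reference[cat_rows]) &
      !vapply(tm$levels[cat_rows], is.null, logical(1))
    if (!all(ok)) {
      abort("Categorical terms must declare `level`, `reference` and the full `levels` set.")
    }
    for (p in unique(tm$predictor[cat_rows])) {
      rows <- tm[cat_rows & tm$predictor == p, ]
      lev_sets <- unique(lapply(rows$levels, as.character))
      if (length(lev_sets) != 1L || length(unique(rows$reference)) != 1L) {
        abort(paste0("Categorical predictor `", p,
                     "` declares inconsistent level sets or references."))
      }
      if (rows$reference[1] %in% rows$level) {
        abort(paste0("Reference level of `", p,
                     "` must not also appear as a coded level."))
      }
    }
  }
  cont <- tm$type == "continuous"
  if (any(cont) && any(tm$scale[cont] <= 0)) {
    abort("Continuous term `scale` divisors must be positive.")
  }
  x
}

#' Load a packaged model specification
#'
#' The package ships the two published post-AKI prediction models, each in its
#' original (derivation) and refitted (validation-cohort) version, with
#' coefficients stored as natural logs of the published odds ratios at printed
#' precision:
#' * `aberdeen_original`, `aberdeen_refit` — 90-day death-or-readmission model
#'   for all hospital survivors;
#' * `alberta_original`, `alberta_refit` — 1-year CKD G4-G5 progression model
#'   for AKI survivors;
#' * `synthetic_grampian_truth` — a package-constructed generating model used
#'   by the cohort simulator (not a published model; see its `notes`).
#'
#' Note the published Aberdeen age odds ratio (1.17 per year) is implausibly
#' large for a 1-year unit but is kept exactly as printed; as a consequence the
#' as-printed Aberdeen models predict risks near 1 at typical adult ages.
#'
#' @param name One of the packaged spec names above.
#' @return A [model_spec()].
#' @examples
#' m <- load_model("aberdeen_original")
#' m$intercept # -1.876
#' @export
load_model <- function(name) {
  dir <- system.file("extdata", "models", package = "postaki")
  available <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  if (length(name) != 1L || !name %in% available) {
    abort(paste0("Unknown model `", paste(name, collapse = ","),
                 "`. Available specs: ", paste(available, collapse = ", "), "."))
  }
  read_model_spec(file.path(dir, paste0(name, ".json")))
}

#' Read / write a model specification as JSON
#'
#' Model specs serialize to a small JSON schema (name, label, outcome,
#' intercept, term list with coding and odds ratio) so users can audit the
#' packaged models or add their own. Reloading a written spec reproduces
#' identical predictions on any cohort.
#'
#' @param path File path.
#' @return `read_model_spec()` returns a [model_spec()];
#'   `write_model_spec()` invisibly returns `path`.
#' @export
read_model_spec <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  terms <- purrr::map_dfr(raw$terms, function(t) {
    tibble::tibble(
      predictor = t$predictor,
      type = t$type,
      level = t$level %||% NA_character_,
      reference = t$reference %||% NA_character_,
      levels = list(if (is.null(t$levels)) NULL else
        as.character(unlist(t$levels))),
      scale = t$scale %||% NA_real_,
      degree = t$degree %||% NA_real_,
      coefficient = t$coefficient %||% NA_real_,
      odds_ratio = t$odds_ratio %||% NA_real_
    )
  })
  model_spec(
    name = raw$name, label = raw$label %||% raw$name, outcome = raw$outcome,
    intercept = raw$intercept, terms = terms,
    notes = as.character(unlist(raw$notes %||% character())),
    provenance = raw$provenance
  )
}

#' @rdname read_model_spec
#' @param model A [model_spec()].
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "model_spec"))
  terms <- purrr::pmap(model$terms, function(predictor, type, level, reference,
                                             levels, scale, degree,
                                             coefficient, odds_ratio) {
    t <- list(predictor = predictor, type = type)
    if (type == "categorical") {
      t$levels <- as.list(levels)
      t$reference <- reference
      t$level <- level
    }
    if (type == "continuous") {
      t$scale <- scale
      t$degree <- degree
    }
    t$coefficient <- coefficient
    t$odds_ratio <- odds_ratio
    t
  })
  out <- list(name = model$name, label = model$label, outcome = model$outcome,
              intercept = model$intercept, notes = as.list(model$notes),
              provenance = model$provenance, terms = terms)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

term_label <- function(terms) {
  vapply(seq_len(nrow(terms)), function(i) {
    t <- terms[i, ]
    switch(t$type,
      categorical = paste0(t$predictor, "=", t$level),
      continuous = paste0(
        t$predictor,
        if (t$degree != 1) paste0("^", t$degree) else "",
        if (t$scale != 1) paste0(" (/", format(t$scale), ")") else ""
      ),
      t$predictor
    )
  }, character(1))
}

#' Design matrix of coded predictor values for a model
#'
#' One column per model term, in term order; used by [linear_predictor()] and
#' [refit()]. Errors, rather than silently imputing, when a required predictor
#' column is absent or contains missing values, or when a categorical value
#' falls outside the declared level set.
#'
#' @param data Cohort data frame, one row per subject.
#' @param model A [model_spec()].
#' @return Numeric matrix, `nrow(data)` by `nrow(model$terms)`.
#' @export
model_matrix <- function(data, model) {
  stopifnot(inherits(model, "model_spec"))
  tm <- model$terms
  cols <- lapply(seq_len(nrow(tm)), function(i) {
    t <- tm[i, ]
    if (!t$predictor %in% names(data)) {
      abort(paste0("Cohort is missing required predictor `", t$predictor,
                   "` for model `", model$name, "`."))
    }
    x <- data[[t$predictor]]
    if (anyNA(x)) {
      abort(paste0("Predictor `", t$predictor,
                   "` contains missing values; no silent imputation is done."))
    }
    switch(t$type,
      binary = {
        v <- as.numeric(x)
        if (!all(v %in% c(0, 1))) {
          abort(paste0("Binary predictor `", t$predictor,
                       "` must be 0/1 or logical."))
        }
        v
      },
      count = {
        v <- as.numeric(x)
        if (any(v < 0) || any(v != round(v))) {
          abort(paste0("Count predictor `", t$predictor,
                       "` must hold nonnegative integers."))
        }
        v
      },
      categorical = {
        v <- as.character(x)
        lev <- as.character(t$levels[[1]])
        if (!all(v %in% lev)) {
          abort(paste0("Predictor `", t$predictor, "` has values outside its ",
                       "declared levels {", paste(lev, collapse = ", "), "}."))
        }
        as.numeric(v == t$level)
      },
      continuous = (as.numeric(x) / t$scale)^t$degree
    )
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- term_label(tm)
  mat
}

#' Prognostic index (linear predictor) of a model on a cohort
#'
#' The prognostic index is the model intercept plus the weighted sum of the
#' coded predictor values, with the published coefficients as weights, on the
#' log-odds scale.
#'
#' @inheritParams model_matrix
#' @return Numeric vector, one prognostic index per row of `data`.
#' @export
linear_predictor <- function(data, model) {
  X <- model_matrix(data, model)
  drop(model$intercept + X %*% model$terms$coefficient)
}

#' Score a cohort: prognostic index and predicted risk
#'
#' Adds columns `.pi` (prognostic index, log-odds) and `.risk`
#' (`plogis(.pi)`, strictly inside (0, 1)) to the cohort table.
#'
#' @inheritParams model_matrix
#' @return `data` as a tibble with `.pi` and `.risk` columns appended.
#' @examples
#' cohort <- tibble::tibble(
#'   age = 0, residential_care = 0, rural = 0, prior_admissions = 0,
#'   emergency_admission = 0, aki_stage = "0", baseline_egfr = 0,
#'   cancer = 0, cardiac_failure = 0, diabetes = 0, pulmonary = 0
#' )
#' score_cohort(cohort, load_model("aberdeen_original"))$.risk # plogis(-1.876)
#' @export
score_cohort <- function(data, model) {
  pi <- linear_predictor(data, model)
  dplyr::mutate(tibble::as_tibble(data), .pi = pi, .risk = plogis(pi))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n", sep = "")
  cat("  ", x$label, "\n", sep = "")
  cat("  outcome: ", x$outcome, "\n", sep = "")
  cat("  intercept (log-odds): ", format(x$intercept), "\n", sep = "")
  cat("  terms:\n")
  df <- data.frame(term = term_label(x$terms),
                   coefficient = round(x$terms$coefficient, 4),
                   odds_ratio = round(x$terms$odds_ratio, 3))
  print(df, row.names = FALSE)
  if (!is.null(x$provenance)) {
    cat("  provenance: ", x$provenance$method %||% "?", "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a model specification into its coefficient table
#'
#' @param x A [model_spec()].
#' @param ... Unused.
#' @return A tibble with one row per coded term: `term`, `predictor`, `type`,
#'   `level`, `estimate` (log-odds coefficient) and `odds_ratio`.
#' @method tidy model_spec
#' @export
tidy.model_spec <- function(x, ...) {
  tibble::tibble(
    term = term_label(x$terms),
    predictor = x$terms$predictor,
    type = x$terms$type,
    level = x$terms$level,
    estimate = x$terms$coefficient,
    odds_ratio = x$terms$odds_ratio
  )
}

#' One-row summary of a model specification
#'
#' @param x A [model_spec()].
#' @param ... Unused.
#' @return A one-row tibble: `name`, `outcome`, `intercept`, `n_terms`,
#'   `n_predictors`.
#' @method glance model_spec
#' @export
glance.model_spec <- function(x, ...) {
  tibble::tibble(
    name = x$name, outcome = x$outcome, intercept = x$intercept,
    n_terms = nrow(x$terms), n_predictors = length(unique(x$terms$predictor))
  )
}
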