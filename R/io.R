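#' Read and write capacity-model specification files
#'
#' Models are stored as structured text, JSON or YAML by file extension
#' (`.json` vs `.yaml`/`.yml`), with the schema:
#' ```
#' effect_range:
#'   lower: 0        # magnitude L (lower bound is -L); "inf" allowed
#'   upper: 1        # magnitude U; "inf" allowed
#' causes:
#'   - {label: c1, role: generator, strength: 0.5, max_value: 1}
#' ```
#' Infinity is spelled `"inf"`. `write_model()` followed by `read_model()`
#' is the identity on valid models.
#'
#' @param path File path; extension selects the dialect.
#' @param model A `capacity_model` (for `write_model`).
#' @return `read_model()` returns a validated `capacity_model`;
#'   `write_model()` returns `path` invisibly.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_list(spec)
}

num_field <- function(x, field, where) {
  if (is.null(x)) {
    stop(sprintf("missing field '%s' in %s", field, where), call. = FALSE)
  }
  if (identical(x, "inf") || identical(x, "Inf")) return(Inf)
  if (!is.numeric(x) || length(x) != 1L) {
    stop(sprintf("field '%s' in %s must be a number or \"inf\"", field, where),
         call. = FALSE)
  }
  as.numeric(x)
}

model_from_list <- function(spec) {
  er <- spec$effect_range
  if (is.null(er)) stop("missing field 'effect_range'", call. = FALSE)
  range <- effect_range(num_field(er$lower, "lower", "effect_range"),
                        num_field(er$upper, "upper", "effect_range"))
  causes <- lapply(seq_along(spec$causes), function(i) {
    cs <- spec$causes[[i]]
    where <- sprintf("causes[%d]", i)
    if (is.null(cs$label)) {
      stop("missing field 'label' in ", where, call. = FALSE)
    }
    if (is.null(cs$role) ||
        !cs$role %in% c("generator", "reducer", "blocker")) {
      stop(sprintf(
        "field 'role' in %s must be one of generator, reducer, blocker (got '%s')",
        where, if (is.null(cs$role)) "" else cs$role), call. = FALSE)
    }
    strength <- if (is.null(cs$strength) || isTRUE(is.na(cs$strength))) {
      NA_real_
    } else {
      num_field(cs$strength, "strength", where)
    }
    cause(cs$label, cs$role, strength,
          num_field(if (is.null(cs$max_value)) 1 else cs$max_value,
                    "max_value", where))
  })
  capacity_model(range, causes)
}

model_to_list <- function(model) {
  fmt <- function(x) if (is.finite(x)) x else "inf"
  list(
    effect_range = list(lower = fmt(model$range$lower),
                        upper = fmt(model$range$upper)),
    causes = lapply(unname(model$causes), function(cs) {
      list(label = cs$label, role = cs$role,
           strength = if (is.na(cs$strength)) "NA" else cs$strength,
           max_value = fmt(cs$max_value))
    })
  )
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "capacity_model"))
  spec <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

#' Read and write trial tables as CSV
#'
#' Trial CSVs have one column per cause label plus an `effect` column and
#' one row per trial. When a model is supplied, `read_trials()` checks the
#' header against the model's cause labels and each value against its range,
#' reporting offending row numbers. Numbers are written with 12 significant
#' digits, below every tolerance used by the package.
#'
#' @param path CSV file path.
#' @param model Optional `capacity_model` for validation.
#' @param table A trial table or data frame (for `write_trials`).
#' @return `read_trials()` returns a `trial_table` data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path, model = NULL) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (nrow(tab) == 0L) stop("trial table is empty: ", path, call. = FALSE)
  if (!"effect" %in% names(tab)) {
    stop("trial table must have an 'effect' column", call. = FALSE)
  }
  if (!is.null(model)) {
    labels <- cause_labels(model)
    missing <- setdiff(labels, names(tab))
    extra <- setdiff(names(tab), c(labels, "effect"))
    if (length(missing) || length(extra)) {
      stop("trial columns do not match model causes",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; unknown: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
    mx <- cause_max_values(model)
    for (j in seq_along(labels)) {
      bad <- which(tab[[labels[j]]] < 0 | tab[[labels[j]]] > mx[j] + 1e-12)
      if (length(bad)) {
        stop(sprintf("row %d: cause '%s' value %g outside [0, %g]",
                     bad[1], labels[j], tab[[labels[j]]][bad[1]], mx[j]),
             call. = FALSE)
      }
    }
    L <- model$range$lower; U <- model$range$upper
    if (is.finite(L) && is.finite(U)) {
      bad <- which(tab$effect < -L - 1e-12 | tab$effect > U + 1e-12)
      if (length(bad)) {
        stop(sprintf("row %d: effect value %g outside [%g, %g]",
                     bad[1], tab$effect[bad[1]], -L, U), call. = FALSE)
      }
    }
  }
  structure(tab, class = c("trial_table", "data.frame"))
}

#' @rdname read_trials
#' @export
write_trials <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(lapply(table, function(col) {
    if (is.numeric(col)) signif(col, 12) else col
  }))
  names(out) <- names(table)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
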