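#' Build a lottery table
#'
#' A lottery is a finite set of outcome--probability branches.  Lottery
#' tables are ordinary tibbles with one row per branch and columns
#' `lottery_id`, `outcome`, `probability` (plus an optional `set_id` when
#' several choice sets are stacked).  All model functions take and return
#' these tables, so calls chain with the pipe.
#'
#' Zero-probability branches are removed at construction: in the stochastic
#' representation an impossible outcome has no branch at all, which is not
#' the same object as the limit of a vanishing-probability branch.
#' Duplicate outcomes are kept as separate branches — the model is
#' branch-based and coalescing would change its predictions.
#'
#' @param id Lottery label.
#' @param outcomes Numeric vector of monetary outcomes (may be negative).
#' @param probabilities Numeric vector of branch probabilities, same length
#'   as `outcomes`; must sum to 1 within `1e-6` (then normalized exactly).
#' @return A tibble of class `srdt_lotteries` with one row per branch.
#' @examples
#' lottery("L1", c(96, 14, 12), c(0.90, 0.05, 0.05))
#' @export
lottery <- function(id, outcomes, probabilities) {
  stopifnot(length(outcomes) == length(probabilities))
  as_lotteries(tibble::tibble(
    lottery_id = as.character(id),
    outcome = as.numeric(outcomes),
    probability = as.numeric(probabilities)
  ))
}

#' Combine lotteries into a choice set
#'
#' Stacks two or more lottery tables and validates the choice-set
#' restrictions: at least two lotteries, and not all of them degenerate
#' (the Luce ratio form is not meant to arbitrate between sure outcomes).
#'
#' @param ... Lottery tables (from [lottery()] or [as_lotteries()]).
#' @return A validated `srdt_lotteries` tibble.
#' @examples
#' choice_set(
#'   lottery("L1", c(180, 20), c(0.5, 0.5)),
#'   lottery("L2", c(180, 30, 15), c(0.5, 0.25, 0.25))
#' )
#' @export
choice_set <- function(...) {
  x <- dplyr::bind_rows(...)
  as_lotteries(x, choice_set = TRUE)
}

new_lotteries <- function(x) {
  class(x) <- unique(c("srdt_lotteries", class(tibble::as_tibble(x))))
  x
}

#' Validate and normalize a lottery table
#'
#' Checks the branch invariants (finite outcomes, probabilities in
#' \eqn{[0,1]} summing to 1 within `1e-6` per lottery), drops
#' zero-probability branches with a warning, and rescales probabilities so
#' each lottery sums to exactly 1.
#'
#' @param x A data frame with columns `lottery_id`, `outcome`,
#'   `probability` and optionally `set_id`.
#' @param choice_set If `TRUE`, additionally require at least two lotteries
#'   (per `set_id` if present) and that not all of them are degenerate.
#' @return The normalized `srdt_lotteries` tibble.
#' @export
as_lotteries <- function(x, choice_set = FALSE) {
  x <- tibble::as_tibble(x)
  need <- c("lottery_id", "outcome", "probability")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("lottery table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$lottery_id <- as.character(x$lottery_id)
  if (!is.numeric(x$outcome) || !is.numeric(x$probability)) {
    stop("`outcome` and `probability` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x$outcome))) {
    stop("all outcomes must be finite", call. = FALSE)
  }
  if (any(is.na(x$probability) | x$probability < 0 | x$probability > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }

  grp <- if ("set_id" %in% names(x)) c("set_id", "lottery_id") else "lottery_id"

  sums <- x |>
    dplyr::summarise(s = sum(.data$probability), .by = dplyr::all_of(grp))
  bad <- sums[abs(sums$s - 1) > 1e-6, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop("branch probabilities must sum to 1 (within 1e-6); off for lottery ",
         paste(bad$lottery_id, collapse = ", "),
         " (sum ", paste(signif(bad$s, 8), collapse = ", "), ")",
         call. = FALSE)
  }

  if (any(x$probability == 0)) {
    warning("dropping zero-probability branch(es): no branch is built for an ",
            "impossible outcome", call. = FALSE)
    x <- x[x$probability > 0, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    stop("every lottery needs at least one positive-probability branch",
         call. = FALSE)
  }
  x <- x |>
    dplyr::mutate(probability = .data$probability / sum(.data$probability),
                  .by = dplyr::all_of(grp))

  if (choice_set) {
    check_one_set <- function(tab) {
      ids <- unique(tab$lottery_id)
      if (length(ids) < 2) {
        stop("a choice set needs at least 2 lotteries", call. = FALSE)
      }
      deg <- is_degenerate(tab)
      if (all(deg$degenerate)) {
        stop("all lotteries are degenerate (sure outcomes): the Luce ratio ",
             "form excludes choices between sure things", call. = FALSE)
      }
      invisible(tab)
    }
    if ("set_id" %in% names(x)) {
      x |>
        dplyr::group_split(.data$set_id) |>
        purrr::walk(check_one_set)
    } else {
      check_one_set(x)
    }
  }
  new_lotteries(x)
}

#' Flag degenerate (sure-outcome) lotteries
#'
#' A lottery is degenerate when it has exactly one positive-probability
#' branch, i.e. it pays one outcome with certainty.  Two branches carrying
#' the same outcome are still two branches, so such a lottery is not
#' degenerate.
#'
#' @param x A lottery table.
#' @return A tibble with one row per lottery: `lottery_id` (and `set_id`
#'   if present) and logical `degenerate`.
#' @export
is_degenerate <- function(x) {
  grp <- if ("set_id" %in% names(x)) c("set_id", "lottery_id") else "lottery_id"
  x |>
    tibble::as_tibble() |>
    dplyr::summarise(degenerate = sum(.data$probability > 0) == 1L,
                     .by = dplyr::all_of(grp))
}

#' Read lotteries from JSON or CSV
#'
#' JSON schema: `{"lotteries": [{"id": ..., "branches": [{"outcome": ...,
#' "probability": ...}, ...]}, ...]}`.  CSV schema: columns `lottery_id`,
#' `outcome`, `probability`, one row per branch (an optional `set_id`
#' column is carried through).
#'
#' @param path File path (or, for JSON, a literal JSON string).
#' @param format `"auto"` (by file extension), `"json"` or `"csv"`.
#' @param choice_set Validate as a choice set (default `TRUE`).
#' @return An `srdt_lotteries` tibble.
#' @export
read_lotteries <- function(path, format = c("auto", "json", "csv"),
                           choice_set = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  x <- if (format == "json") {
    parsed <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                       error = function(e) {
                         stop("could not parse lottery JSON: ",
                              conditionMessage(e), call. = FALSE)
                       })
    if (is.null(parsed$lotteries)) {
      stop("lottery JSON must have a top-level \"lotteries\" array",
           call. = FALSE)
    }
    purrr::map_dfr(parsed$lotteries, function(lot) {
      if (is.null(lot$id) || is.null(lot$branches)) {
        stop("each lottery needs \"id\" and \"branches\" fields",
             call. = FALSE)
      }
      branches <- purrr::map_dfr(lot$branches, function(b) {
        if (is.null(b$outcome) || is.null(b$probability)) {
          stop("each branch of lottery \"", lot$id,
               "\" needs \"outcome\" and \"probability\"", call. = FALSE)
        }
        tibble::tibble(outcome = as.numeric(b$outcome),
                       probability = as.numeric(b$probability))
      })
      dplyr::mutate(branches, lottery_id = as.character(lot$id),
                    .before = 1)
    })
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  as_lotteries(x, choice_set = choice_set)
}

#' Write lotteries to JSON or CSV
#'
#' Inverse of [read_lotteries()]: `read_lotteries(write_lotteries(x, f))`
#' is the identity on normalized lottery tables.
#'
#' @param x A lottery table.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_lotteries <- function(x, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  x <- as_lotteries(x)
  if (format == "csv") {
    readr::write_csv(x, path)
  } else {
    lots <- x |>
      dplyr::group_split(.data$lottery_id) |>
      purrr::map(function(tab) {
        list(id = tab$lottery_id[[1]],
             branches = purrr::map2(tab$outcome, tab$probability,
                                    ~list(outcome = .x, probability = .y)))
      })
    jsonlite::write_json(list(lotteries = lots), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Generate random choice sets
#'
#' Draws reproducible random choice sets for property tests and recovery
#' studies: outcomes uniform on `outcome_range`, branch probabilities from
#' a flat (uniform) simplex via normalized exponentials.
#'
#' @param n_sets Number of choice sets.
#' @param lotteries_per_set Lotteries in each set (default 2).
#' @param branches_per_lottery Length-2 integer range, e.g. `c(2, 3)`.
#' @param outcome_range Length-2 numeric interval; may span negatives.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An `srdt_lotteries` tibble with a `set_id` column.
#' @export
generate_random_lotteries <- function(n_sets,
                                      lotteries_per_set = 2,
                                      branches_per_lottery = c(2, 3),
                                      outcome_range = c(-100, 100),
                                      seed = 1L) {
  if (length(branches_per_lottery) != 2 ||
      branches_per_lottery[1] > branches_per_lottery[2] ||
      branches_per_lottery[1] < 1) {
    stop("`branches_per_lottery` must be a non-empty range c(lo, hi)",
         call. = FALSE)
  }
  if (length(outcome_range) != 2 || outcome_range[1] > outcome_range[2]) {
    stop("`outcome_range` must be a non-empty interval c(lo, hi)",
         call. = FALSE)
  }
  if (n_sets < 1 || lotteries_per_set < 2) {
    stop("need n_sets >= 1 and lotteries_per_set >= 2", call. = FALSE)
  }
  withr_seed(seed, {
    purrr::map_dfr(seq_len(n_sets), function(s) {
      purrr::map_dfr(seq_len(lotteries_per_set), function(l) {
        k <- if (branches_per_lottery[1] == branches_per_lottery[2]) {
          branches_per_lottery[1]
        } else {
          sample(seq(branches_per_lottery[1], branches_per_lottery[2]), 1)
        }
        # Exp(1) draws normalized to the simplex are uniform on it
        w <- stats::rexp(k)
        tibble::tibble(
          set_id = sprintf("set%03d", s),
          lottery_id = sprintf("L%d", l),
          outcome = stats::runif(k, outcome_range[1], outcome_range[2]),
          probability = w / sum(w)
        )
      })
    }) |> as_lotteries()
  })
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

split_sets <- function(x) {
  if ("set_id" %in% names(x)) {
    split(tibble::as_tibble(x), x$set_id)
  } else {
    list(tibble::as_tibble(x))
  }
}
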