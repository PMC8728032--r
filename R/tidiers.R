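# broom-style tidiers for the test-result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn mardia_test Tidy a single MVN test result into a one-row
#'   tibble.
#' @param x,... Tidier arguments.
#' @export
tidy.mvn_test_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    null_method = x$null_method,
    n_resamples = x$n_resamples
  )
}

#' @export
glance.mvn_test_result <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, p = x$p, p_value = x$p_value)
}

#' @describeIn mvn_battery Tidy a battery into one row per test (failed
#'   methods get `NA` statistics and an `error` message).
#' @param x,... Tidier arguments.
#' @export
tidy.mvn_battery <- function(x, ...) {
  dplyr::bind_rows(lapply(x, function(r) {
    if (inherits(r, "mvn_test_failure")) {
      tibble::tibble(
        method = r$method, statistic = NA_real_, p_value = NA_real_,
        null_method = NA_character_, n_resamples = NA_integer_,
        error = r$message
      )
    } else {
      tidy(r)
    }
  }))
}

#' @export
glance.mvn_battery <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_methods = nrow(td),
    n_failed = sum(!is.na(td[["error"]] %||% rep(NA, 0))),
    min_p_value = suppressWarnings(min(td$p_value, na.rm = TRUE))
  )
}

#' @describeIn global_test Tidy a single GSA test result into a one-row
#'   tibble.
#' @param x,... Tidier arguments.
#' @export
tidy.gsa_test_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    null_method = x$null_method,
    n_resamples = x$n_resamples,
    note = x$note %||% NA_character_
  )
}

#' @describeIn run_gsa Tidy a battery into one row per test.
#' @param x,... Tidier arguments.
#' @export
tidy.gsa_battery <- function(x, ...) {
  dplyr::bind_rows(lapply(x, function(r) {
    if (inherits(r, "gsa_test_failure")) {
      tibble::tibble(
        method = r$method, statistic = NA_real_, p_value = NA_real_,
        null_method = NA_character_, n_resamples = NA_integer_,
        note = paste("error:", r$message)
      )
    } else {
      tidy(r)
    }
  }))
}

#' @export
glance.gsa_battery <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_methods = nrow(td),
    n_failed = sum(is.na(td$p_value)),
    min_p_value = suppressWarnings(min(td$p_value, na.rm = TRUE))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
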