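# The accounts cube: CHE amounts indexed by provider type, health-care
# function, financing scheme, disease chapter and age bin, stored in long
# format (one populated cell per row). Marginal views are ordinary grouped
# sums, so additivity across dimensions holds by construction; validation
# checks the level sets and non-negativity.

cube_dims <- c("provider_type", "fn", "financing", "disease_class", "age_bin")

#' Construct an accounts cube
#'
#' @param cells Data frame with columns `provider_type`, `fn` (health-care
#'   function), `financing`, `disease_class`, `age_bin`, `amount_cny`.
#'   Duplicate keys are summed.
#' @param currency Currency label of the amounts (default `"CNY"`).
#' @param year Accounting year.
#' @param scope Population scope label, e.g. `"total_population"` or
#'   `"children_0_14"`.
#' @param sources Optional tibble of financing-source amounts
#'   (`provider_type`, `source`, `amount_cny`) carried as metadata for the
#'   funding-schemes report; not part of the cube total.
#' @return A tibble of class `accounts_cube` with metadata attributes.
#' @export
accounts_cube <- function(cells, currency = "CNY", year = NA_integer_,
                          scope = "total_population", sources = NULL) {
  stopifnot(all(c(cube_dims, "amount_cny") %in% names(cells)))
  cells <- tibble::as_tibble(cells)
  bad_fn <- setdiff(unique(cells$fn), che_functions)
  if (length(bad_fn) > 0) {
    stop("unknown function label(s): ", paste(bad_fn, collapse = ", "), call. = FALSE)
  }
  bad_fin <- setdiff(unique(cells$financing), che_financing_schemes)
  if (length(bad_fin) > 0) {
    stop("unknown financing scheme(s): ", paste(bad_fin, collapse = ", "), call. = FALSE)
  }
  if (any(cells$amount_cny < -1e-9 * max(1, sum(abs(cells$amount_cny))))) {
    stop("negative cube cell(s): internal consistency error", call. = FALSE)
  }
  cells$amount_cny <- pmax(cells$amount_cny, 0) # clamp float dust
  cells <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cube_dims))) |>
    dplyr::summarise(amount_cny = sum(.data$amount_cny), .groups = "drop") |>
    dplyr::filter(.data$amount_cny != 0)
  structure(cells,
    class = c("accounts_cube", class(tibble::tibble())),
    currency = currency, year = year, scope = scope, sources = sources
  )
}

#' Grand total of an accounts cube
#' @param cube An [accounts_cube()].
#' @return Total amount in the cube's currency.
#' @export
cube_total <- function(cube) sum(cube$amount_cny)

#' Marginal view of an accounts cube
#'
#' Sums cell amounts over all dimensions not named, e.g.
#' `cube_margin(cube, "provider_type")` gives spending per provider type.
#'
#' @param cube An [accounts_cube()].
#' @param ... Dimension names to keep (character).
#' @return Tibble with the kept dimensions and `amount_cny`.
#' @export
cube_margin <- function(cube, ...) {
  keep <- c(...)
  stopifnot(all(keep %in% cube_dims))
  tibble::as_tibble(cube) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keep))) |>
    dplyr::summarise(amount_cny = sum(.data$amount_cny), .groups = "drop")
}

#' @export
print.accounts_cube <- function(x, ...) {
  cat(sprintf(
    "<accounts_cube> %s %s, scope %s: %d cells, total %.2f\n",
    attr(x, "currency"), as.character(attr(x, "year")), attr(x, "scope"),
    nrow(x), cube_total(x)
  ))
  NextMethod()
}

#' Serialize / read an accounts cube as a long-format delimited table
#'
#' @param cube An [accounts_cube()].
#' @param path File path for the comma-separated cell table.
#' @return `write_cube` returns `path` invisibly; `read_cube` an
#'   [accounts_cube()] (metadata restored from a YAML sidecar `<path>.meta`).
#' @export
write_cube <- function(cube, path) {
  readr::write_csv(tibble::as_tibble(cube), path)
  meta <- list(
    currency = attr(cube, "currency"),
    year = as.integer(attr(cube, "year")),
    scope = attr(cube, "scope")
  )
  yaml::write_yaml(meta, paste0(path, ".meta"), precision = 15)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_path <- paste0(path, ".meta")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  accounts_cube(cells,
    currency = meta$currency %||% "CNY",
    year = meta$year %||% NA_integer_,
    scope = meta$scope %||% "total_population"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
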