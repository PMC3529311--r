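#' Construct a validated country-by-quintile dataset
#'
#' A `country_dataset` holds the five wealth-quintile strata of one country:
#' U5MR (deaths per 1000 live births), current CCM coverage (fraction of
#' pneumonia episodes receiving antibiotics), annual live births in the
#' stratum, pneumonia case fatality rate (deaths per episode) and
#' cause-of-death proportions.  Quintile 1 is the wealthiest, quintile 5 the
#' poorest.  Coverage, births, CFR and cause proportions may be left `NA`
#' when they are to be supplied later (by configuration or by the synthetic
#' generator); whenever present they are validated.
#'
#' @param country country label.
#' @param quintiles data frame with columns `quintile` (1..5, exactly one
#'   each), `u5mr`, and optionally `coverage`, `births`, `cfr` and one
#'   `cause:<label>` column per cause.
#' @param overall_u5mr optional national U5MR (the "Overall" column of a
#'   published table).
#' @return object of class `country_dataset`.
#' @examples
#' d <- country_dataset("Toyland",
#'   data.frame(quintile = 1:5, u5mr = c(20, 30, 40, 50, 60)))
#' quintile_ratio(d)
#' @export
country_dataset <- function(country, quintiles, overall_u5mr = NA_real_) {
  stopifnot(is.character(country), length(country) == 1L)
  x <- structure(list(country = country,
                      quintiles = as.data.frame(quintiles),
                      overall_u5mr = as.numeric(overall_u5mr)),
                 class = "country_dataset")
  validate_country_dataset(x)
}

#' Validate a country dataset against the model invariants
#'
#' Checks quintile cardinality (exactly one profile per ordinal 1..5),
#' non-negative U5MR and births, coverage in \[0, 1\], CFR in (0, 1\], and
#' that cause proportions lie in \[0, 1\] and sum to one within `1e-9` in
#' every quintile.  Errors name the offending field and row.
#'
#' @param x a `country_dataset`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_country_dataset <- function(x) {
  q <- x$quintiles
  if (!"quintile" %in% names(q) || !"u5mr" %in% names(q))
    stop("country dataset needs 'quintile' and 'u5mr' columns", call. = FALSE)
  if (nrow(q) != 5L || !setequal(q$quintile, 1:5))
    stop(sprintf("country '%s': expected exactly 5 quintiles (1..5), got %s",
                 x$country, paste(q$quintile, collapse = ",")), call. = FALSE)
  q <- q[order(q$quintile), , drop = FALSE]
  rownames(q) <- NULL
  for (col in intersect(c("u5mr", "coverage", "births", "cfr"), names(q)))
    if (!is.numeric(q[[col]]))
      stop_field(col, x$country, "non-numeric values")
  if (anyNA(q$u5mr) || any(q$u5mr < 0))
    stop_field("u5mr", which(is.na(q$u5mr) | q$u5mr < 0),
               "must be a non-negative number")
  if ("coverage" %in% names(q)) {
    bad <- !is.na(q$coverage) & (q$coverage < 0 | q$coverage > 1)
    if (any(bad)) stop_field("coverage", which(bad), "must lie in [0,1]")
  }
  if ("births" %in% names(q)) {
    bad <- !is.na(q$births) & q$births < 0
    if (any(bad)) stop_field("births", which(bad), "must be non-negative")
  }
  if ("cfr" %in% names(q)) {
    bad <- !is.na(q$cfr) & (q$cfr <= 0 | q$cfr > 1)
    if (any(bad)) stop_field("cfr", which(bad), "must lie in (0,1]")
  }
  cc <- cause_columns(q)
  if (length(cc)) {
    cm <- as.matrix(q[cc])
    if (!is.numeric(cm)) stop_field("cause proportions", x$country,
                                    "non-numeric values")
    present <- rowSums(is.na(cm)) == 0L
    if (any(cm[present, ] < 0 | cm[present, ] > 1))
      stop_field("cause proportions", which(present)[
        rowSums(cm[present, , drop = FALSE] < 0 |
                cm[present, , drop = FALSE] > 1) > 0],
        "each proportion must lie in [0,1]")
    sums <- rowSums(cm[present, , drop = FALSE])
    off <- abs(sums - 1) > 1e-9
    if (any(off))
      stop_field("cause proportions", which(present)[off], sprintf(
        "must sum to 1 within 1e-9 (got %s)",
        paste(format(sums[off]), collapse = ", ")))
  }
  x$quintiles <- q
  invisible(x)
}

cause_columns <- function(df) grep("^cause:", names(df), value = TRUE)

#' @export
print.country_dataset <- function(x, ...) {
  cat(sprintf("<country_dataset> %s (overall U5MR %s)\n", x$country,
              ifelse(is.na(x$overall_u5mr), "-", format(x$overall_u5mr))))
  print(x$quintiles, ...)
  invisible(x)
}

#' @export
as.data.frame.country_dataset <- function(x, ...) {
  cbind(country = x$country, x$quintiles)
}

#' Read country-by-quintile tables from CSV
#'
#' Expects a comma-separated, dot-decimal, UTF-8 file with a header row and
#' columns `country`, `quintile`, `u5mr` and optionally `coverage`,
#' `births`, `cfr` and `cause:<label>` columns.  Each country must
#' contribute exactly five rows (quintiles 1..5).  All dataset invariants
#' are enforced on load; violations raise an error naming the field and row.
#'
#' @param path path to the CSV file.
#' @return a named list of [country_dataset()] objects, one per country, in
#'   file order.
#' @seealso [write_country_table()] for the inverse.
#' @export
read_country_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  req <- c("country", "quintile", "u5mr")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(names(df), "country")
  for (col in num_cols) {
    if (is.logical(df[[col]]) && all(is.na(df[[col]]))) {
      df[[col]] <- as.numeric(df[[col]])  # all-NA column read as logical
    } else if (!is.numeric(df[[col]])) {
      bad <- is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]])
      stop_field(col, which(bad), "non-numeric cell")
    }
  }
  out <- lapply(split(df, factor(df$country, unique(df$country))),
                function(d) {
    ov <- if ("overall_u5mr" %in% names(d)) d$overall_u5mr[1] else NA_real_
    country_dataset(d$country[1],
                    d[setdiff(names(d), c("country", "overall_u5mr"))], ov)
  })
  out[unique(df$country)]
}

#' Write country datasets to CSV
#'
#' Serialises one dataset or a list of datasets in the layout accepted by
#' [read_country_table()], at full double precision so that a read/write
#' round trip is the identity.
#'
#' @param x a `country_dataset` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(x, path) {
  if (inherits(x, "country_dataset")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(d) {
    out <- cbind(country = d$country, d$quintiles)
    out$overall_u5mr <- d$overall_u5mr
    out
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Quintile ratio: U5MR of the poorest over the wealthiest quintile
#'
#' The quintile ratio (QR) is a standard equity summary: the closer to 1,
#' the more equitable the mortality distribution; values above 1 mean the
#' poorest fifth fares worse.
#'
#' @param dataset a [country_dataset()].
#' @return positive scalar, `u5mr(Q5) / u5mr(Q1)`.
#' @examples
#' quintile_ratio(exemplar_datasets()[["Nigeria"]])  # 219 / 87
#' @export
quintile_ratio <- function(dataset) {
  stopifnot(inherits(dataset, "country_dataset"))
  q <- dataset$quintiles
  u1 <- q$u5mr[q$quintile == 1]
  u5 <- q$u5mr[q$quintile == 5]
  if (u1 == 0)
    stop("quintile ratio undefined: wealthiest-quintile U5MR is 0",
         call. = FALSE)
  u5 / u1
}
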