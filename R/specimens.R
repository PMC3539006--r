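#' @importFrom stats complete.cases pnorm dnorm qnorm sd cor.test rnorm uniroot setNames
#' @importFrom utils combn packageVersion
NULL

# Tidy specimen-table schema. One row per measured tissue: the whole lichen
# thallus or a biont isolated from it.
specimen_columns <- c(
  "specimen_id", "population_id", "site", "substrate_class", "tissue",
  "d15N", "d13C", "N_wt_pct", "C_wt_pct", "CN_ratio"
)
required_numeric <- c("d15N")
substrate_levels <- c("organic", "minerogenic")
tissue_levels <- c("whole_lichen", "photobiont", "mycobiont")

# Raw substrate strings accepted in input files; anything else is an error,
# never guessed. Bark, wood and moss are organic growth surfaces; concrete,
# stone, brick and metal are minerogenic.
substrate_alias <- c(
  organic = "organic", minerogenic = "minerogenic",
  bark = "organic", wood = "organic", moss = "organic",
  concrete = "minerogenic", stone = "minerogenic",
  brick = "minerogenic", metal = "minerogenic"
)

# Stored delta values are per-mil; values outside [-100, 100] almost always
# mean a raw ratio slipped in, so they are rejected.
delta_limits <- c(-100, 100)

map_substrate <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(substrate_alias[key])
  bad <- is.na(out) & !is.na(key) & nzchar(key)
  list(value = out, bad = bad)
}

#' Validate a table of specimen measurements
#'
#' Checks a data frame against the tidy specimen schema: enumerated
#' `substrate_class` (raw substrate names such as "bark" or "stone" are
#' mapped to organic/minerogenic), enumerated `tissue`, per-mil delta values
#' within \[-100, 100\], positive mass fractions, and consistency of
#' `CN_ratio` with `C_wt_pct / N_wt_pct`. A missing `CN_ratio` is filled in
#' from C and N when both are present. Every offending row is reported by
#' number; nothing is silently dropped.
#'
#' @param x A data frame with columns `specimen_id`, `population_id`, `site`,
#'   `substrate_class`, `tissue`, `d15N`, `d13C`, `N_wt_pct`, `C_wt_pct`,
#'   `CN_ratio` (the last three may be `NA`).
#' @return A validated tibble with canonical substrate classes and `CN_ratio`
#'   filled where derivable, rows in input order.
#' @export
validate_specimens <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(
    c("specimen_id", "population_id", "substrate_class", "tissue", "d15N"),
    names(x)
  )
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(specimen_columns, names(x))) {
    x[[col]] <- if (col %in% c("site")) NA_character_ else NA_real_
  }
  x <- x[, specimen_columns]
  x$specimen_id <- as.character(x$specimen_id)
  x$population_id <- as.character(x$population_id)
  x$site <- as.character(x$site)

  sub <- map_substrate(x$substrate_class)
  if (any(sub$bad)) {
    rows <- which(sub$bad)
    stop(sprintf(
      "row %s: unknown substrate_class %s (accepted: %s; raw substrates %s are mapped automatically)",
      paste(rows, collapse = ", "),
      paste(sQuote(unique(x$substrate_class[rows])), collapse = ", "),
      paste(substrate_levels, collapse = "/"),
      paste(setdiff(names(substrate_alias), substrate_levels), collapse = ", ")
    ), call. = FALSE)
  }
  x$substrate_class <- sub$value
  if (any(is.na(x$substrate_class))) {
    stop("row ", paste(which(is.na(x$substrate_class)), collapse = ", "),
         ": missing substrate_class", call. = FALSE)
  }

  tis <- tolower(trimws(as.character(x$tissue)))
  bad_tis <- !(tis %in% tissue_levels)
  if (any(bad_tis)) {
    stop(sprintf("row %s: tissue must be one of %s",
                 paste(which(bad_tis), collapse = ", "),
                 paste(tissue_levels, collapse = "/")), call. = FALSE)
  }
  x$tissue <- tis

  for (col in c("d15N", "d13C", "N_wt_pct", "C_wt_pct", "CN_ratio")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  if (any(is.na(x$d15N))) {
    stop("row ", paste(which(is.na(x$d15N)), collapse = ", "),
         ": missing required numeric field d15N", call. = FALSE)
  }
  for (col in c("d15N", "d13C")) {
    out_of_range <- !is.na(x[[col]]) &
      (x[[col]] < delta_limits[1] | x[[col]] > delta_limits[2])
    if (any(out_of_range)) {
      stop("row ", paste(which(out_of_range), collapse = ", "), ": ", col,
           " outside [-100, 100] per mil; raw isotope ratios must be converted",
           " with delta_from_ratios()", call. = FALSE)
    }
  }
  for (col in c("N_wt_pct", "C_wt_pct")) {
    nonpos <- !is.na(x[[col]]) & x[[col]] <= 0
    if (any(nonpos)) {
      stop("row ", paste(which(nonpos), collapse = ", "), ": ", col,
           " must be > 0 when present", call. = FALSE)
    }
  }

  derivable <- is.na(x$CN_ratio) & !is.na(x$C_wt_pct) & !is.na(x$N_wt_pct)
  x$CN_ratio[derivable] <- x$C_wt_pct[derivable] / x$N_wt_pct[derivable]
  both <- !is.na(x$CN_ratio) & !is.na(x$C_wt_pct) & !is.na(x$N_wt_pct)
  inconsistent <- both &
    abs(x$CN_ratio - x$C_wt_pct / x$N_wt_pct) > 1e-6 * abs(x$CN_ratio)
  if (any(inconsistent)) {
    stop("row ", paste(which(inconsistent), collapse = ", "),
         ": CN_ratio inconsistent with C_wt_pct / N_wt_pct", call. = FALSE)
  }
  x
}

#' Read specimen measurements from a tidy CSV file
#'
#' The interchange format is comma-separated UTF-8 with a "." decimal
#' separator, one header row, and blank cells for missing values. Rows are
#' validated with [validate_specimens()]; row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of specimen records.
#' @seealso [write_specimens()]
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  # numeric conversion through R's strtod, which rounds correctly, so
  # write -> read round trips are exact to the last bit
  for (col in intersect(c("d15N", "d13C", "N_wt_pct", "C_wt_pct", "CN_ratio"),
                        names(raw))) {
    txt <- raw[[col]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- !is.na(txt) & nzchar(trimws(txt)) & is.na(num)
    if (any(bad)) {
      stop("malformed CSV at ", path, " (row ", which(bad)[1], ", column ",
           col, "): expected a number, got ", sQuote(txt[which(bad)[1]]),
           call. = FALSE)
    }
    raw[[col]] <- num
  }
  validate_specimens(raw)
}

#' Write specimen measurements to a tidy CSV file
#'
#' @param x A specimen tibble (validated or validatable).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(x, path) {
  x <- validate_specimens(x)
  out <- x
  for (col in c("d15N", "d13C", "N_wt_pct", "C_wt_pct", "CN_ratio")) {
    out[[col]] <- format_roundtrip(x[[col]])
  }
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

# Shortest decimal representation that parses back to the identical double,
# so write -> read round trips preserve full precision.
format_roundtrip <- function(x) {
  s <- trimws(formatC(x, digits = 15, format = "g"))
  bad <- is.finite(x) & suppressWarnings(as.numeric(s)) != x
  if (any(bad)) s[bad] <- trimws(formatC(x[bad], digits = 17, format = "g"))
  s[is.na(x)] <- NA_character_
  s
}

#' Match whole-lichen and isolated-biont measurements by population
#'
#' The mixing model needs, for each lichen population, the whole-lichen
#' measurement together with the photobiont and mycobiont isolated from the
#' same material. This function pairs them up: one triplet per
#' `population_id` holding exactly one record of each tissue. Populations
#' with an incomplete tissue set are excluded and listed in the attached
#' exclusion report; a duplicated tissue within a population is an error
#' because the pairing would be ambiguous.
#'
#' @param records A validated specimen tibble containing `whole_lichen`,
#'   `photobiont` and `mycobiont` rows.
#' @return A tibble with one row per complete population and columns
#'   `population_id`, `substrate_class`, `site`, and for each slot (lichen
#'   `L`, photobiont `P`, mycobiont `M`) the measured `d15N_*`, `d13C_*`,
#'   `N_*` (N wt%) and `CN_*` values. Photobiont and mycobiont rows must
#'   carry `N_wt_pct`. The exclusion report is attached as attribute
#'   `"excluded"` (tibble: `population_id`, `reason`).
#' @export
group_triplets <- function(records) {
  records <- validate_specimens(records)
  pops <- unique(records$population_id)
  rows <- vector("list", length(pops))
  excluded <- list()
  for (i in seq_along(pops)) {
    pop <- pops[i]
    chunk <- records[records$population_id == pop, ]
    counts <- table(factor(chunk$tissue, levels = tissue_levels))
    if (any(counts > 1)) {
      stop("population ", pop, ": duplicate ",
           paste(names(counts)[counts > 1], collapse = ", "),
           " record(s); pairing is ambiguous", call. = FALSE)
    }
    if (any(counts == 0)) {
      excluded[[length(excluded) + 1]] <- tibble::tibble(
        population_id = pop,
        reason = paste("missing", paste(names(counts)[counts == 0], collapse = ", "))
      )
      next
    }
    if (length(unique(chunk$substrate_class)) != 1) {
      stop("population ", pop, ": records disagree on substrate_class",
           call. = FALSE)
    }
    L <- chunk[chunk$tissue == "whole_lichen", ]
    P <- chunk[chunk$tissue == "photobiont", ]
    M <- chunk[chunk$tissue == "mycobiont", ]
    if (is.na(P$N_wt_pct) || is.na(M$N_wt_pct)) {
      excluded[[length(excluded) + 1]] <- tibble::tibble(
        population_id = pop,
        reason = "biont record lacks N_wt_pct (required by the mixing model)"
      )
      next
    }
    rows[[i]] <- tibble::tibble(
      population_id = pop,
      substrate_class = L$substrate_class,
      site = L$site,
      d15N_L = L$d15N, d13C_L = L$d13C, N_L = L$N_wt_pct, CN_L = L$CN_ratio,
      d15N_P = P$d15N, d13C_P = P$d13C, N_P = P$N_wt_pct, CN_P = P$CN_ratio,
      d15N_M = M$d15N, d13C_M = M$d13C, N_M = M$N_wt_pct, CN_M = M$CN_ratio
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      population_id = character(), substrate_class = character(),
      site = character(),
      d15N_L = double(), d13C_L = double(), N_L = double(), CN_L = double(),
      d15N_P = double(), d13C_P = double(), N_P = double(), CN_P = double(),
      d15N_M = double(), d13C_M = double(), N_M = double(), CN_M = double()
    )
  }
  attr(out, "excluded") <- if (length(excluded) > 0) {
    dplyr::bind_rows(excluded)
  } else {
    tibble::tibble(population_id = character(), reason = character())
  }
  out
}

#' Plain-text exclusion report for a triplet table
#'
#' @param triplets Output of [group_triplets()].
#' @return Character scalar describing dropped populations, empty-string when
#'   none were dropped.
#' @export
exclusion_report <- function(triplets) {
  ex <- attr(triplets, "excluded")
  if (is.null(ex) || nrow(ex) == 0) return("")
  paste0("excluded populations:\n",
         paste0("  ", ex$population_id, ": ", ex$reason, collapse = "\n"))
}
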