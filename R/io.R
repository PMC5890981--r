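#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column names and the aliases accepted for GeneMapper-style exports.
# Matching is case-insensitive and ignores spaces/dots/underscores.
.peak_col_aliases <- list(
  sample_id = c("sample_id", "sample", "samplename", "samplefile",
                "samplefilename", "id"),
  size_bp   = c("size_bp", "size", "sizebp", "fragmentsize", "length"),
  intensity = c("intensity", "height", "signal", "signalintensity", "area")
)

.normalize_colname <- function(x) gsub("[ ._-]", "", tolower(x))

.tissue_letters <- c(t = "tail", s = "striatum", c = "cerebellum")

#' Parse a sample identifier into animal, sex and tissue
#'
#' Sample codes follow the supplementary-legend convention, e.g. `BRM2085t`:
#' an alphanumeric animal code containing the sex letter (`M` male, `F`
#' female), with the tissue as the final character: `t` tail, `s` striatum,
#' `c` cerebellum. The animal code is the id minus the tissue letter. Unknown
#' tissue letters or missing sex letters are errors, never guessed.
#'
#' @param id Character vector of sample ids.
#' @return A tibble with columns `sample_id`, `animal`, `sex`
#'   (`"male"`/`"female"`), `tissue` (`"tail"`/`"striatum"`/`"cerebellum"`).
#' @examples
#' parse_sample_id(c("BRM2085t", "BRF0001s"))
#' @export
parse_sample_id <- function(id) {
  stopifnot(is.character(id), length(id) >= 1)
  bad <- !grepl("^[A-Za-z0-9]{2,}$", id)
  if (any(bad)) {
    stop("malformed sample id(s): ", paste(id[bad], collapse = ", "),
         call. = FALSE)
  }
  tissue_letter <- tolower(substr(id, nchar(id), nchar(id)))
  unknown <- !(tissue_letter %in% names(.tissue_letters))
  if (any(unknown)) {
    stop("unrecognized tissue letter in id(s) ",
         paste(id[unknown], collapse = ", "),
         "; allowed final letters: ",
         paste(sprintf("'%s' (%s)", names(.tissue_letters), .tissue_letters),
               collapse = ", "),
         call. = FALSE)
  }
  animal <- substr(id, 1, nchar(id) - 1)
  has_m <- grepl("M", animal, fixed = TRUE)
  has_f <- grepl("F", animal, fixed = TRUE)
  nosex <- !(has_m | has_f)
  if (any(nosex)) {
    stop("no sex letter ('M' or 'F') in sample id(s): ",
         paste(id[nosex], collapse = ", "), call. = FALSE)
  }
  tibble(
    sample_id = id,
    animal = animal,
    sex = ifelse(has_m, "male", "female"),
    tissue = unname(.tissue_letters[tissue_letter])
  )
}

#' Read a fragment-analysis peak table
#'
#' Reads the canonical tab-separated dialect (`sample_id  size_bp  intensity`)
#' or a GeneMapper-style export whose column names match a documented alias
#' set (case/punctuation-insensitive: e.g. `Sample File Name`, `Size`,
#' `Height`). Rows are validated (positive sizes, non-negative finite
#' intensities), duplicate `(sample_id, size_bp)` rows are summed (exports
#' commonly split one peak across dye bins), and points are sorted by size
#' within sample.
#'
#' @param file Path to a TSV file, a literal data string, or a connection
#'   (anything [readr::read_tsv()] accepts); alternatively a data frame
#'   already holding the columns.
#' @return A tibble with columns `sample_id`, `size_bp`, `intensity`, sorted
#'   by sample then size, with strictly increasing `size_bp` within sample.
#' @examples
#' read_peak_table(I("sample_id\tsize_bp\tintensity\nBRM1M1t\t850.1\t1000\n"))
#' @export
read_peak_table <- function(file) {
  raw <- if (is.data.frame(file)) {
    as_tibble(file)
  } else {
    readr::read_tsv(file, col_types = readr::cols(.default = readr::col_guess()),
                    progress = FALSE, show_col_types = FALSE)
  }
  nm <- .normalize_colname(names(raw))
  idx <- vapply(.peak_col_aliases, function(aliases) {
    hit <- which(nm %in% .normalize_colname(aliases))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing) > 0) {
    stop("peak table is missing required column(s): ",
         paste(missing, collapse = ", "),
         " (aliases accepted, case-insensitive)", call. = FALSE)
  }
  out <- tibble(
    sample_id = as.character(raw[[idx[["sample_id"]]]]),
    size_bp = as.numeric(raw[[idx[["size_bp"]]]]),
    intensity = as.numeric(raw[[idx[["intensity"]]]])
  )
  if (nrow(out) == 0L) return(out)

  bad_size <- which(!is.finite(out$size_bp) | out$size_bp <= 0)
  if (length(bad_size) > 0) {
    stop("non-positive or non-finite size_bp at row(s) ",
         paste(utils::head(bad_size, 5), collapse = ", "), call. = FALSE)
  }
  bad_int <- which(!is.finite(out$intensity) | out$intensity < 0)
  if (length(bad_int) > 0) {
    stop("negative or non-finite intensity at row(s) ",
         paste(utils::head(bad_int, 5), collapse = ", "), call. = FALSE)
  }
  out |>
    group_by(.data$sample_id, .data$size_bp) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    arrange(.data$sample_id, .data$size_bp)
}

#' Build a cohort manifest pairing tissue samples with germline baselines
#'
#' Every non-tail sample must be pairable with the tail (weaning) sample of
#' the same animal; the tail modal repeat is that animal's germline baseline.
#' The `design` table assigns each animal its treatment group and the age at
#' which the tissue was taken.
#'
#' @param samples A tibble of sample metadata with at least `sample_id`; if
#'   `animal`/`sex`/`tissue` are absent they are parsed from the ids. A peak
#'   table works too (extra columns are ignored, ids deduplicated).
#' @param design A tibble with columns `animal`, `group` and optionally
#'   `age_weeks` (default `NA`). Groups are free-form labels such as
#'   `"WT-Veh"`, `"R6/2-Veh"`, `"R6/2-XJB"`.
#' @return A `cag_manifest` tibble: one row per sample with `sample_id`,
#'   `animal`, `sex`, `tissue`, `group`, `age_weeks`, and for non-tail rows
#'   `baseline_id` (the paired tail sample).
#' @export
build_manifest <- function(samples, design) {
  stopifnot(is.data.frame(samples), is.data.frame(design))
  if (!"sample_id" %in% names(samples)) {
    stop("`samples` must contain a sample_id column", call. = FALSE)
  }
  meta <- parse_sample_id(unique(samples$sample_id))
  if (!all(c("animal", "group") %in% names(design))) {
    stop("`design` must contain columns animal and group", call. = FALSE)
  }
  design <- as_tibble(design)
  if (!"age_weeks" %in% names(design)) design$age_weeks <- NA_integer_
  if (any(!is.na(design$age_weeks) & design$age_weeks < 0)) {
    stop("age_weeks must be >= 0", call. = FALSE)
  }

  unknown_animal <- setdiff(meta$animal, design$animal)
  if (length(unknown_animal) > 0) {
    stop("sample(s) for animal(s) not in design: ",
         paste(unknown_animal, collapse = ", "), call. = FALSE)
  }
  tails <- meta |> filter(.data$tissue == "tail")
  dup_tail <- tails$animal[duplicated(tails$animal)]
  if (length(dup_tail) > 0) {
    stop("more than one tail baseline for animal(s): ",
         paste(unique(dup_tail), collapse = ", "), call. = FALSE)
  }
  out <- meta |>
    left_join(design[, c("animal", "group", "age_weeks")], by = "animal") |>
    left_join(tails |> select(animal = "animal", baseline_id = "sample_id"),
              by = "animal") |>
    mutate(baseline_id = ifelse(.data$tissue == "tail", NA_character_,
                                .data$baseline_id))
  orphan <- out |> filter(.data$tissue != "tail", is.na(.data$baseline_id))
  if (nrow(orphan) > 0) {
    stop("tissue sample(s) without a tail baseline for animal(s): ",
         paste(unique(orphan$animal), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("cag_manifest", class(out))
  out
}

#' Write / read a repeat-length distribution table
#'
#' Canonical TSV dialect `sample_id  cag  weight` with floats serialized to 6
#' significant digits; `read_distribution_table()` round-trips it.
#'
#' @param dist A tibble with columns `sample_id` (or `animal`), a repeat
#'   column (`cag` or `dcag`) and `weight`.
#' @param file Output path.
#' @return `file`, invisibly; the reader returns a tibble.
#' @export
write_distribution_table <- function(dist, file) {
  stopifnot(is.data.frame(dist))
  num <- vapply(dist, is.numeric, logical(1))
  out <- dist
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' @rdname write_distribution_table
#' @export
read_distribution_table <- function(file) {
  readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
}
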