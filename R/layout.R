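# 96-well plate layouts (SBS convention: rows A-H, columns 1-12).

plate_rows <- LETTERS[1:8]

well_name <- function(row, col) paste0(plate_rows[row], col)

parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Ha-h])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed well address: ", paste(well[bad], collapse = ", "))
  row <- match(toupper(vapply(m, `[`, "", 2L)), plate_rows)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > 12L)) {
    stop("well column out of 1-12 range: ", paste(well[col < 1L | col > 12L], collapse = ", "))
  }
  data.frame(row = row, col = col)
}

#' Lay a condition set out across 96-well plates
#'
#' Tiles the condition list (one "matrix unit") `n_units` times across
#' `n_plates` 96-well plates, filling wells unit by unit in row-major order
#' (A1, A2, ..., A12, B1, ...) and running on across plate boundaries. Each
#' unit is one species/replicate slot: the 63-condition Screen 1 unit copied
#' 24 times over 18 plates gives the full 1,512-well run; the 183-condition
#' Screen 2 unit copied 9 times gives the 1,647-well run.
#'
#' @param conditions character vector of condition ids, or a data frame with
#'   a `condition_id` column (e.g. [generate_screen1()] output or
#'   `as.data.frame()` of a [generate_bbd()] design).
#' @param n_units number of species/replicate slots to tile.
#' @param n_plates number of 96-well plates available.
#' @param species optional character vector (length `n_units`) of species ids;
#'   default placeholders `"sp01"`, ... Units sharing a species id get
#'   incrementing replicate indices.
#' @return An object of class `plate_layout`: list with `assignments` (data
#'   frame `plate`, `well`, `row`, `col`, `condition_id`, `species_id`,
#'   `replicate`) and `n_plates`. Unassigned wells are not listed; use
#'   [layout_summary()] for the conservation accounting.
#' @export
#' @examples
#' lay <- layout_run(generate_screen1(), n_units = 24, n_plates = 18)
#' nrow(lay$assignments)  # 1512
layout_run <- function(conditions, n_units, n_plates, species = NULL) {
  ids <- if (is.data.frame(conditions)) conditions$condition_id else as.character(conditions)
  if (is.null(ids) || !length(ids)) stop("no conditions to lay out")
  n_units <- as.integer(n_units)
  n_plates <- as.integer(n_plates)
  need <- length(ids) * n_units
  avail <- 96L * n_plates
  if (need > avail) {
    stop(sprintf("layout capacity exceeded: need %d wells, have %d (%d plates)",
                 need, avail, n_plates))
  }
  if (is.null(species)) species <- sprintf("sp%02d", seq_len(n_units))
  if (length(species) != n_units) stop("species must have length n_units")
  replicate <- stats::ave(seq_along(species), species, FUN = seq_along)
  pos <- seq_len(need) - 1L # 0-based well stream across plates
  plate <- pos %/% 96L + 1L
  within <- pos %% 96L
  row <- within %/% 12L + 1L
  col <- within %% 12L + 1L
  unit <- rep(seq_len(n_units), each = length(ids))
  assignments <- data.frame(
    plate = plate,
    well = well_name(row, col),
    row = plate_rows[row], col = col,
    condition_id = rep(ids, times = n_units),
    species_id = species[unit],
    replicate = replicate[unit],
    stringsAsFactors = FALSE
  )
  structure(list(assignments = assignments, n_plates = n_plates),
            class = "plate_layout")
}

#' Per-layout well accounting
#'
#' @param layout a `plate_layout`.
#' @return List with `assigned`, `empty` and `total` well counts
#'   (`assigned + empty == 96 * n_plates`).
#' @export
layout_summary <- function(layout) {
  total <- 96L * layout$n_plates
  assigned <- nrow(layout$assignments)
  list(assigned = assigned, empty = total - assigned, total = total)
}

#' @export
print.plate_layout <- function(x, ...) {
  s <- layout_summary(x)
  cat(sprintf("plate_layout: %d plates, %d assigned wells, %d empty\n",
              x$n_plates, s$assigned, s$empty))
  invisible(x)
}

#' Write / read a plate layout CSV
#'
#' Columns: `plate`, `well` (letter row + 1-based column, e.g. `"A1"`),
#' `condition_id`, `species_id`, `replicate`. Reading validates addresses
#' (rows A-H, columns 1-12) and rejects duplicate wells; write-then-read is
#' an identity on the layout.
#'
#' @param layout a `plate_layout`.
#' @param file path.
#' @return `read_layout` returns a `plate_layout`.
#' @export
write_layout <- function(layout, file) {
  df <- layout$assignments[, c("plate", "well", "condition_id", "species_id", "replicate")]
  df <- cbind(df, n_plates = layout$n_plates)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_layout
#' @export
read_layout <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("plate", "well", "condition_id", "species_id", "replicate")
  if (!all(need %in% names(df))) {
    stop("layout CSV must have columns: ", paste(need, collapse = ", "))
  }
  n_plates <- if ("n_plates" %in% names(df) && nrow(df)) df$n_plates[1L] else
    if (nrow(df)) max(df$plate) else 0L
  if (nrow(df)) {
    rc <- parse_well(df$well)
    key <- paste(df$plate, toupper(df$well))
    if (anyDuplicated(key)) {
      stop("duplicate well assignment: ", key[duplicated(key)][1L])
    }
    assignments <- data.frame(
      plate = as.integer(df$plate),
      well = toupper(df$well),
      row = plate_rows[rc$row], col = rc$col,
      condition_id = df$condition_id,
      species_id = df$species_id,
      replicate = as.integer(df$replicate),
      stringsAsFactors = FALSE
    )
  } else {
    assignments <- data.frame(
      plate = integer(), well = character(), row = character(), col = integer(),
      condition_id = character(), species_id = character(), replicate = integer(),
      stringsAsFactors = FALSE
    )
  }
  structure(list(assignments = assignments, n_plates = as.integer(n_plates)),
            class = "plate_layout")
}
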