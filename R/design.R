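# Screen designs: full-factorial N/P (Screen 1) and Box-Behnken (Screen 2).

# Default Screen 1 nitrogen level sets, in mM of compound. Concentrations are
# adjusted for the number of N atoms per molecule, so the two-N sources
# (urea, NH4NO3) run at roughly half the single-N molar levels.
screen1_nitrogen_defaults <- function() {
  list(
    NaNO3  = c(0, 4.4, 8.8, 13.2, 30),
    NH4Cl  = c(0, 4.2, 8.4, 12.6, 30),
    urea   = c(0, 3.8, 7.5, 11.3, 15),
    NH4NO3 = c(0, 3.8, 7.5, 11.3, 15)
  )
}

screen1_phosphate_defaults <- function() c(0, 2, 10)

#' Generate the Screen 1 full-factorial nitrogen/phosphate condition set
#'
#' Screen 1 crosses four nitrogen sources at five concentrations each with
#' three phosphate (KH2PO4) levels, giving 60 photoautotrophic conditions;
#' three mixotrophic TAP-medium positive controls complete the 63-well matrix
#' unit. The zero-nitrogen rows of the four sources are chemically the same
#' medium; they are kept as distinct conditions (preserving the plate layout
#' and the printed condition count) but flagged `zero_n_duplicate`.
#'
#' @param nitrogen named list of nitrogen level sets in mM of compound
#'   (default: the built-in Table of screen levels).
#' @param phosphate KH2PO4 levels in mM (default 0, 2, 10).
#' @param include_tap add the 3 TAP control conditions (default TRUE).
#' @param n_tap number of TAP controls when included.
#' @return Data frame of conditions with columns `condition_id`, `role`,
#'   `n_source`, `n_mM`, `p_mM`, `is_tap_control`, `zero_n_duplicate`.
#' @export
#' @examples
#' s1 <- generate_screen1()
#' nrow(s1)                 # 63
#' sum(s1$is_tap_control)   # 3
generate_screen1 <- function(nitrogen = screen1_nitrogen_defaults(),
                             phosphate = screen1_phosphate_defaults(),
                             include_tap = TRUE, n_tap = 3L) {
  known <- names(screen1_nitrogen_defaults())
  if (is.null(names(nitrogen)) || any(!nzchar(names(nitrogen)))) {
    stop("nitrogen level sets must be a named list")
  }
  unknown <- setdiff(names(nitrogen), known)
  if (length(unknown)) {
    stop("unknown nitrogen source(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  }
  if (any(unlist(nitrogen) < 0) || any(phosphate < 0)) {
    stop("concentrations must be non-negative")
  }
  rows <- list()
  for (src in names(nitrogen)) {
    for (n in nitrogen[[src]]) {
      for (p in phosphate) {
        rows[[length(rows) + 1L]] <- data.frame(
          n_source = src, n_mM = n, p_mM = p,
          is_tap_control = FALSE,
          zero_n_duplicate = (n == 0 && src != names(nitrogen)[1L]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (include_tap && n_tap > 0L) {
    tap <- data.frame(
      n_source = "TAP", n_mM = NA_real_, p_mM = NA_real_,
      is_tap_control = TRUE, zero_n_duplicate = FALSE,
      stringsAsFactors = FALSE
    )
    out <- rbind(out, tap[rep(1L, n_tap), ])
  }
  out$role <- ifelse(out$is_tap_control, "tap_control", "screen1")
  out$condition_id <- sprintf("S1-%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("condition_id", "role", "n_source", "n_mM", "p_mM",
          "is_tap_control", "zero_n_duplicate")]
}

# Incomplete-block tables for the three-level Box-Behnken designs. Each
# element is the list of factor blocks varied together at +/-1 while all
# other factors sit at 0. Structures follow the classical catalogue of
# three-level incomplete factorials (Box & Behnken 1960): paired blocks for
# k = 3..5, triples for k = 6, 7, 9 and 4-factor blocks for k = 10 (10 blocks
# of 4 -> 160 non-centre runs). The k = 7 triples are a cyclic Steiner system
# (every pair once); k = 9 is the AG(2,3) triple system plus one repeated
# parallel class (15 blocks, 120 runs); k = 10 is the cyclic development of
# {1, 2, 5, 7} mod 10, under which every factor appears in exactly 4 blocks
# and every pair co-occurs, making all 66 second-order terms estimable.
bbd_block_table <- function(k) {
  cyc <- function(base, k) lapply(seq_len(k), function(i) sort((base + i - 2L) %% k + 1L))
  switch(as.character(k),
    "3" = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
    "4" = list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 4L), c(2L, 3L)),
    "5" = utils::combn(5L, 2L, simplify = FALSE),
    "6" = cyc(c(1L, 2L, 4L), 6L),
    "7" = cyc(c(1L, 2L, 4L), 7L),
    "9" = list(c(1L, 2L, 3L), c(4L, 5L, 6L), c(7L, 8L, 9L),
               c(1L, 4L, 7L), c(2L, 5L, 8L), c(3L, 6L, 9L),
               c(1L, 5L, 9L), c(2L, 6L, 7L), c(3L, 4L, 8L),
               c(1L, 6L, 8L), c(2L, 4L, 9L), c(3L, 5L, 7L),
               c(1L, 2L, 3L), c(4L, 5L, 6L), c(7L, 8L, 9L)),
    "10" = cyc(c(1L, 2L, 5L, 7L), 10L),
    stop("no Box-Behnken block table for k = ", k,
         " (supported: 3-7, 9, 10)")
  )
}

#' Generate a Box-Behnken design
#'
#' Builds the three-level incomplete factorial used for Screen 2: each block
#' of the published block table varies its factors over all +/-1 combinations
#' with every other factor at the coded mid level 0, and `n_center` all-zero
#' centre-point runs are appended. For the ten-factor screen this gives
#' 10 blocks x 2^4 = 160 runs plus the centre points (180 with the default
#' 20 centres); each factor is non-zero in exactly 64 runs, split 32/32
#' between -1 and +1.
#'
#' Row order is canonical: blocks in table order, within-block sign
#' combinations in binary counting order (first blocked factor fastest),
#' centre points last.
#'
#' @param k number of factors (3-7, 9 or 10).
#' @param n_center number of centre-point replicates (default 20, the Screen 2
#'   configuration; the centre point is the best Screen 1 medium).
#' @param factors optional factor table ([nutrient_factors()] subset with
#'   `role == "factor"`) used to name columns and resolve concentrations;
#'   defaults to the built-in ten-nutrient table when `k = 10`.
#' @return An object of class `bbd_design`: a list with `coded` (runs x k
#'   matrix of -1/0/+1), `k`, `n_center`, `role` (per-run `"screen2"` or
#'   `"center"`), `condition_id`, `factors` and, when a factor table is
#'   available, `concentrations_mM` (runs x k matrix).
#' @export
#' @examples
#' d <- generate_bbd(k = 10, n_center = 20)
#' nrow(d$coded)                      # 180
#' sum(rowSums(d$coded != 0) == 0)    # 20
generate_bbd <- function(k = 10L, n_center = 20L, factors = NULL) {
  k <- as.integer(k)
  n_center <- as.integer(n_center)
  if (n_center < 0L) stop("n_center must be >= 0")
  blocks <- bbd_block_table(k)
  if (is.null(factors) && k == 10L) {
    factors <- nutrient_factors()
    factors <- factors[factors$role == "factor", ]
  }
  fnames <- if (!is.null(factors)) factors$name[seq_len(k)] else paste0("X", seq_len(k))
  rows <- vector("list", sum(2L^lengths(blocks)) + n_center)
  idx <- 1L
  for (b in blocks) {
    s <- length(b)
    for (i in 0L:(2L^s - 1L)) {
      r <- rep(0, k)
      bits <- as.integer(intToBits(i))[seq_len(s)]
      r[b] <- ifelse(bits == 1L, 1, -1)
      rows[[idx]] <- r
      idx <- idx + 1L
    }
  }
  for (i in seq_len(n_center)) {
    rows[[idx]] <- rep(0, k)
    idx <- idx + 1L
  }
  coded <- do.call(rbind, rows)
  colnames(coded) <- fnames
  role <- c(rep("screen2", nrow(coded) - n_center), rep("center", n_center))
  out <- list(
    coded = coded, k = k, n_center = n_center, role = role,
    condition_id = sprintf("S2-%03d", seq_len(nrow(coded))),
    factors = factors
  )
  if (!is.null(factors)) {
    conc <- coded
    for (j in seq_len(k)) {
      conc[, j] <- code_to_concentration(factors[j, ], coded[, j])
    }
    out$concentrations_mM <- conc
  }
  class(out) <- "bbd_design"
  out
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d factors, %d runs (%d centre points)\n",
              x$k, nrow(x$coded), x$n_center))
  cat("Factors:", paste(colnames(x$coded), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.bbd_design <- function(x, ...) {
  df <- data.frame(condition_id = x$condition_id, role = x$role,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$coded))
  if (!is.null(x$concentrations_mM)) {
    conc <- as.data.frame(x$concentrations_mM)
    names(conc) <- paste0(colnames(x$coded), "_mM")
    df <- cbind(df, conc)
  }
  df
}

coded_matrix <- function(design) {
  if (inherits(design, "bbd_design")) return(design$coded)
  m <- as.matrix(design)
  if (is.null(colnames(m))) colnames(m) <- paste0("X", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' Build the second-order response-surface model matrix
#'
#' Expands a coded design into the model matrix of the quadratic response
#' surface y = X beta + epsilon: an intercept, the m linear terms, the
#' m(m-1)/2 cross-product terms (pairs in lexicographic order) and the m
#' squared terms, in that fixed column order — p = 1 + 2m + m(m-1)/2 columns
#' (66 for m = 10).
#'
#' @param design a `bbd_design` or a numeric matrix/data frame of coded levels.
#' @return Numeric matrix with named columns (`(Intercept)`, factor names,
#'   `A:B` cross products, `A^2` squares).
#' @export
#' @examples
#' X <- build_model_matrix(generate_bbd(10, 20))
#' dim(X)  # 180 x 66
build_model_matrix <- function(design) {
  D <- coded_matrix(design)
  if (nrow(D) < 1L) stop("design must have at least one row")
  m <- ncol(D)
  nm <- colnames(D)
  X <- cbind(`(Intercept)` = rep(1, nrow(D)), D)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        X <- cbind(X, D[, i] * D[, j])
        colnames(X)[ncol(X)] <- paste0(nm[i], ":", nm[j])
      }
    }
  }
  sq <- D^2
  colnames(sq) <- paste0(nm, "^2")
  cbind(X, sq)
}

#' Write / read a design CSV
#'
#' The design CSV has columns `condition_id`, `role` and one coded column per
#' factor, plus resolved `<factor>_mM` columns when concentrations are known.
#'
#' @param design a `bbd_design` or a Screen 1 condition data frame.
#' @param file path to write to / read from.
#' @return `write_design` returns `file` invisibly; `read_design` returns a
#'   data frame (coded columns restored as numeric).
#' @export
write_design <- function(design, file) {
  df <- if (inherits(design, "bbd_design")) as.data.frame(design) else design
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_design
#' @export
read_design <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
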