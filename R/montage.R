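# Electrode montage and the 2D grid used to spatialise per-channel features.

#' The 17-channel vigilance montage
#'
#' The recording montage used throughout the package: twelve posterior
#' electrodes (CP1, CPZ, CP2, P1, PZ, P2, PO3, POZ, PO4, O1, OZ, O2) and six
#' temporal electrodes (FT7, FT8, T7, T8, TP7, TP8) of the international
#' 10-20 placement system, with CPZ serving as the reference. Dropping the
#' reference leaves 17 recording channels.
#'
#' @param include_reference If `TRUE`, return all 18 electrode names
#'   including the CPZ reference.
#' @return Character vector of channel names.
#' @examples
#' length(vigilance_channels())   # 17
#' @export
vigilance_channels <- function(include_reference = FALSE) {
  posterior <- c("CP1", "CPZ", "CP2", "P1", "PZ", "P2",
                 "PO3", "POZ", "PO4", "O1", "OZ", "O2")
  temporal <- c("FT7", "FT8", "T7", "T8", "TP7", "TP8")
  all <- c(temporal, posterior)
  if (include_reference) all else setdiff(all, "CPZ")
}

#' Electrode-to-grid mapping
#'
#' Places each channel of the 17-channel montage at a distinct (row, col)
#' cell of a 2D scalp grid. The `dense` default is the minimal 6 x 9 matrix
#' that covers the montage: rows run front to back (FT, T, TP, CP, P, and a
#' shared parieto-occipital/occipital bottom row), columns left to right by
#' 10-20 laterality. Grid cells without an electrode stay zero in every
#' feature tensor. The `sparse` style embeds the same electrodes in a
#' 9 x 9 full-scalp grid with one row per electrode ring, trading more
#' zero padding for a layout closer to true scalp geometry; it exists for
#' ablation comparisons against the dense default.
#'
#' The mapping is data, not code: any tibble with columns `channel`, `row`,
#' `col` (and attributes `h`, `w`) is accepted wherever a grid is expected,
#' and [read_grid_csv()]/[write_grid_csv()] round-trip it through a plain
#' CSV so alternative layouts can be versioned alongside an analysis.
#'
#' @param style `"dense"` (6 x 9, default) or `"sparse"` (9 x 9).
#' @return A tibble with columns `channel`, `row`, `col` and attributes
#'   `h`, `w` giving the grid dimensions.
#' @examples
#' g <- electrode_grid()
#' attr(g, "h"); attr(g, "w")
#' @export
electrode_grid <- function(style = c("dense", "sparse")) {
  style <- match.arg(style)
  if (style == "dense") {
    g <- tibble::tribble(
      ~channel, ~row, ~col,
      "FT7", 1L, 1L,  "FT8", 1L, 9L,
      "T7",  2L, 1L,  "T8",  2L, 9L,
      "TP7", 3L, 1L,  "TP8", 3L, 9L,
      "CP1", 4L, 4L,  "CP2", 4L, 6L,
      "P1",  5L, 4L,  "PZ",  5L, 5L,  "P2",  5L, 6L,
      "PO3", 6L, 2L,  "POZ", 6L, 3L,  "PO4", 6L, 4L,
      "O1",  6L, 6L,  "OZ",  6L, 7L,  "O2",  6L, 8L
    )
    attr(g, "h") <- 6L
    attr(g, "w") <- 9L
  } else {
    g <- tibble::tribble(
      ~channel, ~row, ~col,
      "FT7", 3L, 1L,  "FT8", 3L, 9L,
      "T7",  4L, 1L,  "T8",  4L, 9L,
      "TP7", 5L, 1L,  "TP8", 5L, 9L,
      "CP1", 6L, 4L,  "CP2", 6L, 6L,
      "P1",  7L, 4L,  "PZ",  7L, 5L,  "P2",  7L, 6L,
      "PO3", 8L, 3L,  "POZ", 8L, 5L,  "PO4", 8L, 7L,
      "O1",  9L, 4L,  "OZ",  9L, 5L,  "O2",  9L, 6L
    )
    attr(g, "h") <- 9L
    attr(g, "w") <- 9L
  }
  validate_grid(g)
  g
}

validate_grid <- function(grid) {
  stopifnot(all(c("channel", "row", "col") %in% names(grid)))
  h <- attr(grid, "h"); w <- attr(grid, "w")
  if (is.null(h) || is.null(w)) {
    stop("grid must carry `h` and `w` attributes", call. = FALSE)
  }
  if (any(grid$row < 1 | grid$row > h | grid$col < 1 | grid$col > w)) {
    stop("grid coordinates fall outside the declared h x w extent",
         call. = FALSE)
  }
  key <- paste(grid$row, grid$col)
  if (anyDuplicated(key)) {
    stop("grid maps two channels to the same cell: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(grid$channel)) stop("duplicate channel in grid",
                                        call. = FALSE)
  invisible(grid)
}

#' Read or write an electrode grid as CSV
#'
#' The CSV holds columns `channel,row,col`; the grid extent is stored in a
#' `# h w` comment on the first line.
#'
#' @param path File path.
#' @param grid A grid tibble as returned by [electrode_grid()].
#' @return `read_grid_csv()` returns the grid tibble.
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1L)
  hw <- as.integer(strsplit(sub("^#\\s*", "", header), "\\s+")[[1]])
  g <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                         stringsAsFactors = FALSE))
  g$row <- as.integer(g$row); g$col <- as.integer(g$col)
  attr(g, "h") <- hw[1]; attr(g, "w") <- hw[2]
  validate_grid(g)
  g
}

#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(grid, path) {
  validate_grid(grid)
  writeLines(sprintf("# %d %d", attr(grid, "h"), attr(grid, "w")), path)
  suppressWarnings(utils::write.table(
    grid[, c("channel", "row", "col")], path, sep = ",",
    row.names = FALSE, col.names = TRUE, quote = FALSE, append = TRUE))
  invisible(path)
}
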