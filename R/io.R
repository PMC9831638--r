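# Plain-text persistence: patch corpora and threshold tables as CSV with a
# JSON metadata sidecar, class models and discriminants as JSON.

#' Write / read a patch corpus as CSV
#'
#' Patches in rows, with a JSON sidecar (`<path>.json`) recording the width
#' and provenance attributes.
#'
#' @param patches Patch matrix.
#' @param path CSV path.
#' @param meta Named list of extra metadata.
#' @export
ac_write_patches <- function(patches, path, meta = list()) {
  patches <- as_patch_matrix(patches)
  utils::write.table(patches, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta$W <- attr(patches, "W") %||% as.integer(round(sqrt(ncol(patches))))
  jsonlite_write(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname ac_write_patches
#' @export
ac_read_patches <- function(path) {
  X <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(X) <- NULL
  meta <- jsonlite_read(paste0(path, ".json"))
  attr(X, "W") <- meta$W
  X
}

#' Write / read a threshold table as CSV + JSON
#'
#' @param table An `ac_threshold_table`.
#' @param path CSV path (thresholds, grid points in rows).
#' @export
ac_write_table <- function(table, path) {
  utils::write.table(table$xi, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(task = table$task, psi = table$psi, n_mc = table$n_mc,
               seed = table$seed, valid = table$valid, cost = table$cost,
               grid = if (is.matrix(table$grid)) {
                 list(row = table$grid[, 1], col = table$grid[, 2])
               } else table$grid)
  jsonlite_write(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname ac_write_table
#' @export
ac_read_table <- function(path) {
  xi <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(xi) <- NULL
  meta <- jsonlite_read(paste0(path, ".json"))
  grid <- if (is.list(meta$grid)) {
    cbind(row = meta$grid$row, col = meta$grid$col)
  } else meta$grid
  structure(list(xi = xi, grid = grid, task = meta$task, psi = meta$psi,
                 cost = unlist(meta$cost), valid = unlist(meta$valid),
                 n_mc = meta$n_mc, seed = meta$seed),
            class = "ac_threshold_table")
}

jsonlite_write <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("the jsonlite package is required for metadata sidecars")
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}

jsonlite_read <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("the jsonlite package is required for metadata sidecars")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a template image as plain-text PGM
#'
#' Templates (or any single patch) persist as ASCII PGM (`P2`) with the
#' original real-valued range recorded in a comment line, so the round trip
#' restores values up to the 16-bit quantization of the format. Users can
#' substitute their own object template through this loader.
#'
#' @param patch Pixel vector or `W x W` matrix.
#' @param path File path.
#' @export
ac_write_pgm <- function(patch, path) {
  v <- as_patch_vector(patch)
  W <- as.integer(round(sqrt(length(v))))
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) 65535 / (hi - lo) else 0
  q <- as.integer(round((v - lo) * scale))
  img <- matrix(q, W, W, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("# range %.17g %.17g", lo, hi),
               sprintf("%d %d", W, W), "65535"), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname ac_write_pgm
#' @export
ac_read_pgm <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "P2") abort("only ASCII PGM (P2) files are supported")
  rng <- as.numeric(strsplit(sub("# range ", "", lines[2]), " ")[[1]])
  dims <- as.integer(strsplit(lines[3], " ")[[1]])
  # pixel values stream in row-major image order, matching the patch layout
  vals <- scan(text = paste(lines[-(1:4)], collapse = " "), quiet = TRUE)
  lo <- rng[1]; hi <- rng[2]
  out <- if (hi > lo) lo + vals * (hi - lo) / 65535 else rep(lo, length(vals))
  attr(out, "W") <- dims[1]
  out
}
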