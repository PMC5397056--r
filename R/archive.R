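# Plain-text gridded archive: a directory holding the cell table, column
# tilings (from which the grid is rebuilt deterministically), the per-cell
# field table, per-column plume parameters and JSON metadata.  Numeric
# values are written with 17 significant digits so a write/read round trip
# reproduces every field bit-exactly.

fmt_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df
}

read_num_df <- function(path, int_cols = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (nm %in% int_cols) df[[nm]] <- as.integer(df[[nm]])
    else df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

#' Write a field archive to disk
#'
#' @param fields A `cell_fields` object.
#' @param grid The `vr_grid` the fields are defined on.
#' @param path Directory to create/overwrite.
#' @return Invisibly `path`.
#' @export
write_archive <- function(fields, grid, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(fmt_num_df(df), file.path(path, name), row.names = FALSE)
  }
  wr(grid$fine_columns, "fine_columns.csv")
  wr(grid$base_columns, "base_columns.csv")
  wr(fields$fields, "fields.csv")
  wr(fields$plume, "plume.csv")
  cfg <- grid$config
  meta <- list(domain = grid$domain,
               base_size = cfg$base_size,
               level_divisors = cfg$level_divisors,
               min_cell_size = cfg$min_cell_size,
               pop_threshold = cfg$pop_threshold,
               layer_tops = cfg$layer_tops,
               high_res_cap = cfg$high_res_cap,
               generator = fields$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a field archive from disk
#'
#' Rebuilds the grid deterministically from the stored column tilings and
#' configuration, and restores all per-cell fields bit-exactly.
#'
#' @param path Archive directory written by [write_archive()].
#' @return List with elements `grid` (a `vr_grid`) and `fields`
#'   (a `cell_fields`).
#' @export
read_archive <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  cfg <- grid_config(base_size = as.numeric(meta$base_size),
                     level_divisors = as.integer(meta$level_divisors),
                     min_cell_size = as.numeric(meta$min_cell_size),
                     pop_threshold = as.numeric(meta$pop_threshold),
                     layer_tops = as.numeric(meta$layer_tops),
                     high_res_cap = as.numeric(meta$high_res_cap),
                     domain = as.numeric(meta$domain))
  fine <- read_num_df(file.path(path, "fine_columns.csv"), int_cols = "level")
  base <- read_num_df(file.path(path, "base_columns.csv"), int_cols = "level")
  grid <- new_vr_grid(fine, base, meta$domain, cfg)
  f <- read_num_df(file.path(path, "fields.csv"), int_cols = "id")
  plume <- read_num_df(file.path(path, "plume.csv"),
                       int_cols = c("col", "stability_class"))
  fields <- structure(list(fields = f, plume = plume,
                           grid_ref = list(n_cells = nrow(f)),
                           meta = meta$generator, hourly = NULL),
                      class = "cell_fields")
  list(grid = grid, fields = fields)
}
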