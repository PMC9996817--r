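# Plain-text I/O. Tables travel as CSV with the same schemas the generators
# emit; gridded products (flow records, concentration histories) are written
# as long-format CSV with a commented unit header.

read_table_checked <- function(path, required) {
  x <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(required, names(x))
  if (length(miss))
    abort_config(sprintf("'%s' lacks column(s): %s", path,
                         paste(miss, collapse = ", ")))
  x
}

#' Read pipeline input tables from CSV
#'
#' Thin validated readers for the package's table schemas: cosolvent
#' measurements (`methanol_mole_fraction`, `log_kpw_obs`), PRC observations
#' (`compound`, `fraction_retained`, `deployment_days`), exposure outcomes
#' (`treatment`, `tank`, `n`, `dead`), and absorbed amounts with station
#' metadata (`station`, `absorbed_ng`).
#'
#' @param path CSV file; lines starting with `#` are ignored.
#' @return a data frame with the validated schema.
#' @export
read_cosolvent_csv <- function(path) {
  read_table_checked(path, c("methanol_mole_fraction", "log_kpw_obs"))
}

#' @rdname read_cosolvent_csv
#' @export
read_prc_csv <- function(path) {
  read_table_checked(path, c("compound", "fraction_retained", "deployment_days"))
}

#' @rdname read_cosolvent_csv
#' @export
read_outcomes_csv <- function(path) {
  read_table_checked(path, c("treatment", "tank", "n", "dead"))
}

#' @rdname read_cosolvent_csv
#' @export
read_absorbed_csv <- function(path) {
  read_table_checked(path, c("station", "absorbed_ng"))
}

#' Write a flow record or concentration history to CSV
#'
#' `write_flow_csv()` writes the time series of current components
#' (`time_s`, `u_ms`, `v_ms`). `write_history_csv()` writes snapshots in
#' long format (`time_h`, `x_m`, `y_m`, `conc_ngL`), optionally dropping
#' zero cells to keep files small. Units are recorded in `#` header lines.
#'
#' @param flow a [gen_flow_field()] record.
#' @param history a [simulate_dispersal()] result.
#' @param path output file.
#' @param drop_zero omit cells with zero concentration (default TRUE).
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic flow record; u,v in m s-1, time in s", con)
  utils::write.csv(data.frame(time_s = flow$times_s, u_ms = flow$u_ms,
                              v_ms = flow$v_ms),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
write_history_csv <- function(history, path, drop_zero = TRUE) {
  cc <- cell_centres(history$grid)
  d <- dim(history$snapshots)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tracer concentration history; conc in ng L-1, coords in m, time in h", con)
  rows <- lapply(seq_len(d[3L]), function(k) {
    m <- history$snapshots[, , k]
    idx <- if (drop_zero) which(m > 0, arr.ind = TRUE) else
      as.matrix(expand.grid(row = seq_len(d[1L]), col = seq_len(d[2L])))
    if (nrow(idx) == 0L) return(NULL)
    data.frame(time_h = history$times_h[k], x_m = cc$x[idx[, 1L]],
               y_m = cc$y[idx[, 2L]], conc_ngL = m[idx])
  })
  utils::write.csv(do.call(rbind, rows), con, row.names = FALSE)
  invisible(path)
}
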