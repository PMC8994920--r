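# The sliding-window projection frame: at step s the trailing W waves of
# history are stacked over a survivor copy shifted forward by one wave, whose
# last window position is entirely missing except deterministic age and
# constant sex. Window positions are addressed by pseudo-years 9002, 9004,
# ... so that all wave-indexed machinery (column naming, death masking)
# applies unchanged; the mapping to calendar years differs between the two
# blocks and is kept in the frame metadata.

.frame_vars <- c("age", "alive", .outcome_vars, .score_vars, .risk_vars)

pos_years <- function(W) seq(9002L, by = 2L, length.out = W)

panel_to_positions <- function(panel, year_map, vars = .frame_vars) {
  out <- panel[, intersect(.id_vars, names(panel)), drop = FALSE]
  for (j in seq_along(year_map)) {
    from <- as.integer(names(year_map)[j])
    for (v in vars) {
      cl <- wave_col(v, from)
      if (cl %in% names(panel)) out[[wave_col(v, year_map[j])]] <- panel[[cl]]
    }
  }
  out
}

#' Build the first projection frame
#'
#' Stacks the completed observed panel (window positions 1..W) over its
#' survivors shifted forward one wave: the shifted block spans observed waves
#' 2..W plus one wholly new wave at the last window position, missing except
#' age (incremented by 2) and sex (constant). Rows of the shifted block are
#' restricted to individuals alive at the last observed wave.
#'
#' @param panel a completed `analysis_dataset` (scores attached, no residual
#'   missingness at alive waves).
#' @param wave_years the observed wave grid.
#' @return an object of class `projection_frame`.
#' @export
build_projection_frame <- function(panel, wave_years) {
  W <- length(wave_years)
  py <- pos_years(W)
  upper <- panel_to_positions(panel, stats::setNames(py, wave_years))
  alive_last <- panel[[wave_col("alive", wave_years[W])]]
  if (anyNA(alive_last))
    stopf("vital status at wave %d must be complete before projection", wave_years[W])
  surv <- which(alive_last == 1)
  lower <- panel_to_positions(panel[surv, , drop = FALSE],
                              stats::setNames(py[-W], wave_years[-1]))
  lower[[wave_col("age", py[W])]] <-
    panel[[wave_col("age", wave_years[W])]][surv] + 2L
  for (v in setdiff(.frame_vars, "age"))
    lower[[wave_col(v, py[W])]] <- rep(NA_integer_, length(surv))
  lower <- lower[, names(upper), drop = FALSE]
  df <- rbind(upper, lower)
  df$block <- rep(c("history", "project"), c(nrow(upper), nrow(lower)))
  structure(list(df = df, step = 1L, W = W, pos_years = py,
                 proj_year = wave_years[W] + 2L),
            class = "projection_frame")
}

#' Advance a completed projection frame by one step
#'
#' The completed shifted block becomes the new history; its survivors at the
#' last window position, shifted forward one position, become the new block
#' to impute (last position again missing except age and sex). This is the
#' survivor-chain recursion: each step's rows are a subset of the previous
#' step's rows imputed alive.
#'
#' @param frame a `projection_frame` whose projected wave has been completed.
#' @return the next `projection_frame`.
#' @export
advance_frame <- function(frame) {
  py <- frame$pos_years
  W <- frame$W
  done <- frame$df[frame$df$block == "project", , drop = FALSE]
  alive_last <- done[[wave_col("alive", py[W])]]
  if (anyNA(alive_last))
    stopf("projected vital status incomplete; impute the frame before advancing")
  nl <- done[alive_last == 1, , drop = FALSE]
  age_next <- nl[[wave_col("age", py[W])]] + 2L
  for (j in seq_len(W - 1))
    for (v in .frame_vars)
      nl[[wave_col(v, py[j])]] <- nl[[wave_col(v, py[j + 1])]]
  nl[[wave_col("age", py[W])]] <- age_next
  for (v in setdiff(.frame_vars, "age"))
    nl[[wave_col(v, py[W])]] <- rep(NA_integer_, nrow(nl))
  df <- rbind(done, nl)
  df$block <- rep(c("history", "project"), c(nrow(done), nrow(nl)))
  structure(list(df = df, step = frame$step + 1L, W = W, pos_years = py,
                 proj_year = frame$proj_year + 2L),
            class = "projection_frame")
}

#' @export
print.projection_frame <- function(x, ...) {
  nb <- table(x$df$block)
  cat("<projection_frame> step", x$step, "-> year", x$proj_year, "\n")
  cat("  window:", x$W, "waves;", nb[["history"]], "history rows,",
      nb[["project"]], "rows to impute\n")
  invisible(x)
}

# Extract the projected wave (last window position of the shifted block) of
# a completed frame as a per-individual slice labelled with its calendar year.
extract_projected_wave <- function(frame) {
  py <- frame$pos_years
  W <- frame$W
  lower <- frame$df[frame$df$block == "project", , drop = FALSE]
  out <- lower[, intersect(.id_vars, names(lower)), drop = FALSE]
  for (v in .frame_vars) out[[v]] <- lower[[wave_col(v, py[W])]]
  out$year <- frame$proj_year
  rownames(out) <- NULL
  out
}
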