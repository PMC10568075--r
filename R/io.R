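#' Export traced curves and analysis results
#'
#' Deterministic, bit-stable text exports: curves and trajectories as
#' CSV (with a comment header recording the package version and a hash
#' of the configuration used), intersections and bifurcation events as
#' JSON records. Floating point is printed at 12 significant digits.
#'
#' @param pc a `pn_planar` curve.
#' @param path output file.
#' @param config optional named list recorded (hashed) in the header.
#' @return the path, invisibly.
#' @export
write_curve_csv <- function(pc, path, config = NULL) {
  rows <- do.call(rbind, lapply(pc$branches, function(df) {
    df[, c("branch_id", "input", pc$state_names, "u", "v", "residual")]
  }))
  names(rows)[names(rows) == "u"] <- paste0("proj_", tolower(pc$labels[1]))
  names(rows)[names(rows) == "v"] <- paste0("proj_", tolower(pc$labels[2]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(export_header(config), con)
  utils::write.csv(format_df(rows), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param traj a `pn_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path, config = NULL) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  if (!is.null(traj$proj)) {
    df$proj_u <- traj$proj[, 1]
    df$proj_v <- traj$proj[, 2]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(export_header(config), con)
  utils::write.csv(format_df(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param intersections list of `pn_intersection` objects.
#' @export
write_intersections_json <- function(intersections, path, config = NULL) {
  recs <- lapply(intersections, function(z) {
    list(u = z$u, v = z$v,
         state = as.list(z$state),
         residual = z$residual,
         eigenvalues = lapply(as.complex(z$eigenvalues),
                              function(e) list(re = Re(e), im = Im(e))),
         classification = z$classification,
         stability = z$stability,
         angle_deg = z$angle_deg,
         converged = z$converged)
  })
  out <- list(meta = export_meta(config), intersections = recs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param events list of `pn_event` objects.
#' @export
write_events_json <- function(events, path, config = NULL) {
  recs <- lapply(events, function(e) {
    d <- e$diagnostics
    if (!is.null(d$period_series)) d$period_series <- NULL
    list(type = e$type, param = e$param, param_value = e$param_value,
         bracket = e$bracket,
         state = if (!is.null(e$state)) as.list(e$state) else NULL,
         diagnostics = d)
  })
  out <- list(meta = export_meta(config), events = recs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

export_meta <- function(config) {
  list(package = "pseudonull",
       version = as.character(utils::packageVersion("pseudonull")),
       config_hash = config_hash(config))
}

export_header <- function(config) {
  m <- export_meta(config)
  paste0("# pseudonull ", m$version, " config=", m$config_hash)
}

# small deterministic polynomial hash of the deparsed config; avoids a
# digest dependency for what is only a provenance stamp
config_hash <- function(config) {
  if (is.null(config)) return("none")
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

format_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 12, format = "g")
  }
  df
}
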