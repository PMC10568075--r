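#' Model registry
#'
#' Look up a bundled model by name, with optional parameter overrides.
#' Registered names: `"cellcycle"`, `"mapk22_reduced"`, `"mapk22_full"`,
#' `"fhn_toy"`, `"linear_toy"`, `"sn_normal_form"`, `"hopf_normal_form"`.
#'
#' @param name registered model name.
#' @param overrides named numeric vector (or list) of parameter
#'   overrides; unknown parameter names are an error.
#' @return a `pn_system` (or, for `"mapk22_full"`, the plain full-model
#'   list).
#' @export
get_model <- function(name, overrides = NULL) {
  switch(name,
         cellcycle = cellcycle_system(overrides),
         mapk22_reduced = mapk22_reduced_system(overrides),
         mapk22_full = mapk22_full_system(overrides),
         fhn_toy = ,
         linear_toy = ,
         sn_normal_form = ,
         hopf_normal_form = toy_systems(name, overrides),
         stop("unknown model: '", name, "'; see ?get_model"))
}

#' @rdname get_model
#' @export
model_names <- function() {
  c("cellcycle", "mapk22_reduced", "mapk22_full", "fhn_toy",
    "linear_toy", "sn_normal_form", "hopf_normal_form")
}

#' Read a flat key=value parameter file
#'
#' One `name = value` pair per line; blank lines and `#` comments are
#' ignored. This is the on-disk format of the bundled per-model
#' parameter files under `extdata`.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed parameter line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), 0)
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  if (any(!is.finite(vals))) stop("non-numeric parameter value in ", path)
  vals
}
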