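#' Write and read configurations as YAML
#'
#' A single structured text config with sections `muscle` (or `muscles:
#' agonist/antagonist`), `load`, `protocol` and `noise`; all quantities SI.
#' Muscle and load parameter objects round-trip losslessly.
#'
#' @param x A [muscle_params()], [load_params()], or a named list combining
#'   sections (e.g. `list(muscle = , load = , protocol = , noise = )`).
#' @param path File path.
#' @return `write_config()` returns `path` invisibly.
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(strip_config(x), path)
  invisible(path)
}

strip_config <- function(x) {
  if (inherits(x, "muscle_params") || inherits(x, "load_params"))
    return(c(list(.type = class(x)[1]), unclass(x)))
  if (is.list(x)) return(lapply(x, strip_config))
  x
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  restore <- function(x) {
    if (is.list(x) && !is.null(x$.type)) {
      type <- x$.type
      x$.type <- NULL
      if (type == "muscle_params")
        return(do.call(muscle_params,
                       x[setdiff(names(x), c("f_n", "zeta"))]))
      if (type == "load_params")
        return(load_params(M = x$M, b = x$b, k = x$k))
    }
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  restore(yaml::read_yaml(path))
}
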