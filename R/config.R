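#' @title Configuration files
#' @description One configuration schema, serialisable as JSON or YAML,
#'   covering the stance thresholds, smoothing filter, repetition counter
#'   and reflex settings. Loading validates every field and reports precise
#'   error paths.
#' @name config
NULL

#' Load and validate a configuration file
#'
#' Recognised top-level sections (all optional): `thresholds` (fields of
#' [stance_thresholds()]), `filter` ([filter_config()]), `rep`
#' ([rep_config()]), `reflex` ([reflex_config()]), and `min_conf`.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return List with `thresholds`, `filter`, `rep`, `reflex`, `min_conf`,
#'   each a validated config object (defaults where absent).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a mapping/object", call. = FALSE)
  known <- c("thresholds", "filter", "rep", "reflex", "min_conf")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) return(fn())
    if (!is.list(args))
      stop("config error at '", section, "': must be a mapping", call. = FALSE)
    tryCatch(do.call(fn, args),
             error = function(e)
               stop("config error at '", section, "': ",
                    conditionMessage(e), call. = FALSE))
  }
  min_conf <- if (is.null(raw$min_conf)) 0.5 else raw$min_conf
  if (!is.numeric(min_conf) || min_conf < 0 || min_conf > 1)
    stop("config error at 'min_conf': must be in [0, 1]", call. = FALSE)
  list(thresholds = build("thresholds", stance_thresholds),
       filter = build("filter", filter_config),
       rep = build("rep", rep_config),
       reflex = build("reflex", reflex_config),
       min_conf = min_conf)
}
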