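#' Find alternative nutrient sources for a role
#'
#' Implements the exhaustive substitution heuristic for discovering which
#' metabolites can provide a primary nutrient role (carbon or nitrogen): the
#' role's source exchange is removed from the reference medium and every
#' other exchange reaction is substituted in its place (with the same uptake
#' cap); substitutions that still support wild-type growth are alternative
#' sources. The original source is always part of the result.
#'
#' @param model a `metabolic_model`.
#' @param reference a growth-supporting [medium()] containing `role_exchange`.
#' @param role_exchange exchange id currently providing the role (e.g. the
#'   glucose exchange for carbon).
#' @param candidates exchange ids to test; defaults to all exchanges not
#'   already in the reference medium.
#' @param tol growth threshold: objective > `tol` counts as growth.
#' @return character vector of exchange ids able to provide the role.
#' @export
find_alternative_sources <- function(model, reference, role_exchange,
                                     candidates = NULL, tol = 1e-6) {
  stopifnot(inherits(reference, "medium"))
  if (!role_exchange %in% names(reference$uptake)) {
    stop("role exchange '", role_exchange, "' is not in the reference medium")
  }
  model <- cache_dense(model)
  wt <- solve_fba(model, reference)
  if (wt$objective <= tol) {
    stop("reference medium '", reference$name, "' does not support growth")
  }
  cap <- reference$uptake[[role_exchange]]
  if (is.null(candidates)) {
    candidates <- setdiff(exchange_reactions(model), names(reference$uptake))
  }
  base <- reference$uptake[setdiff(names(reference$uptake), role_exchange)]
  hits <- character(0)
  for (ex in candidates) {
    med <- medium(paste0(reference$name, "[", role_exchange, "->", ex, "]"),
                  c(base, stats::setNames(cap, ex)))
    sol <- solve_fba(model, med)
    if (sol$objective > tol) hits <- c(hits, ex)
  }
  union(role_exchange, hits)
}

#' Enumerate minimal media from carbon and nitrogen alternatives
#'
#' Builds the set of minimal environments used for the dispensability
#' analyses: every pairwise combination of a carbon-providing and a
#' nitrogen-providing exchange, substituted into the reference medium (the
#' secondary nutrients are retained), keeping only combinations on which the
#' wild type grows. Each substitute inherits the uptake cap of the source it
#' replaces.
#'
#' @param model a `metabolic_model`.
#' @param reference growth-supporting reference [medium()].
#' @param carbon_exchange,nitrogen_exchange exchange ids providing carbon and
#'   nitrogen in the reference medium.
#' @param carbon_sources,nitrogen_sources candidate source lists; by default
#'   discovered with [find_alternative_sources()].
#' @param allow_same permit media where one exchange provides both roles
#'   (dual-role metabolites such as amino acids).
#' @param tol growth threshold.
#' @return object of class `media_set`: list with `reference`,
#'   `carbon_sources`, `nitrogen_sources`, and `media` (list of [medium()],
#'   named `"<carbon>|<nitrogen>"`).
#' @export
enumerate_minimal_media <- function(model, reference, carbon_exchange,
                                    nitrogen_exchange,
                                    carbon_sources = NULL,
                                    nitrogen_sources = NULL,
                                    allow_same = TRUE, tol = 1e-6) {
  model <- cache_dense(model)
  if (is.null(carbon_sources)) {
    carbon_sources <- find_alternative_sources(model, reference, carbon_exchange, tol = tol)
  }
  if (is.null(nitrogen_sources)) {
    nitrogen_sources <- find_alternative_sources(model, reference, nitrogen_exchange, tol = tol)
  }
  ccap <- reference$uptake[[carbon_exchange]]
  ncap <- reference$uptake[[nitrogen_exchange]]
  base <- reference$uptake[setdiff(names(reference$uptake),
                                   c(carbon_exchange, nitrogen_exchange))]
  media <- list()
  for (cs in carbon_sources) {
    for (ns in nitrogen_sources) {
      if (cs == ns && !allow_same) next
      upt <- if (cs == ns) stats::setNames(max(ccap, ncap), cs)
             else stats::setNames(c(ccap, ncap), c(cs, ns))
      med <- medium(paste0(cs, "|", ns), c(base, upt))
      sol <- solve_fba(model, med)
      if (sol$objective > tol) media[[med$name]] <- med
    }
  }
  structure(list(reference = reference,
                 carbon_sources = carbon_sources,
                 nitrogen_sources = nitrogen_sources,
                 media = media),
            class = "media_set")
}

#' @export
print.media_set <- function(x, ...) {
  cat("<media_set> ", length(x$carbon_sources), " carbon x ",
      length(x$nitrogen_sources), " nitrogen sources -> ",
      length(x$media), " growth-supporting media\n", sep = "")
  invisible(x)
}

parse_uptake <- function(x) {
  vals <- vapply(x, function(v) {
    if (is.character(v) && tolower(v) == "unbounded") Inf else as.numeric(v)
  }, numeric(1))
  stats::setNames(vals, names(x))
}

#' Load media definitions from a structured config
#'
#' Reads a JSON or YAML media configuration with an optional `reference`
#' block (the starting minimal medium, with `carbon_exchange` and
#' `nitrogen_exchange` naming the primary sources) and a `rich_media` list of
#' manually defined environments. Uptake caps are numbers or the keyword
#' `"unbounded"`.
#'
#' @param path path to a `.json` or `.yaml`/`.yml` file, or an equivalent
#'   already-parsed list.
#' @param model optional `metabolic_model`; when given, every referenced
#'   exchange id is validated against the model and unknown ids raise an
#'   error listing them.
#' @return list with `reference` ([medium()] or NULL), `carbon_exchange`,
#'   `nitrogen_exchange`, and `rich_media` (named list of [medium()]).
#' @export
load_media_config <- function(path, model = NULL) {
  cfg <- if (is.character(path)) {
    if (grepl("\\.ya?ml$", path)) yaml_read(path) else jsonlite::read_json(path)
  } else path
  check_ids <- function(ids, what) {
    if (is.null(model)) return(invisible())
    unknown <- setdiff(ids, exchange_reactions(model))
    if (length(unknown)) {
      stop("unknown exchange ids in ", what, ": ", paste(unknown, collapse = ", "))
    }
  }
  reference <- NULL
  if (!is.null(cfg$reference)) {
    upt <- parse_uptake(cfg$reference$uptake)
    check_ids(names(upt), "reference medium")
    reference <- medium(cfg$reference$name %||% "reference", upt)
  }
  rich <- list()
  for (rm in cfg$rich_media %||% list()) {
    upt <- parse_uptake(rm$uptake)
    check_ids(names(upt), paste0("rich medium '", rm$name, "'"))
    rich[[rm$name]] <- medium(rm$name, upt)
  }
  list(reference = reference,
       carbon_exchange = cfg$carbon_exchange %||% NULL,
       nitrogen_exchange = cfg$nitrogen_exchange %||% NULL,
       rich_media = rich)
}

#' Load rich media from a config
#'
#' Convenience wrapper around [load_media_config()] returning only the
#' manually defined (non-enumerated) media.
#'
#' @inheritParams load_media_config
#' @return named list of [medium()] objects.
#' @export
load_rich_media <- function(path, model = NULL) {
  load_media_config(path, model)$rich_media
}

`%||%` <- function(a, b) if (is.null(a)) b else a

yaml_read <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML media configs requires the 'yaml' package")
  }
  yaml::read_yaml(path)
}
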