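#' Candidate model sets
#'
#' The eight candidate models per scale: a core habitat model (clearcut, bog,
#' TRI, distance to water), extended by the three human-infrastructure blocks
#' (forestry roads, public roads, buildings) singly, pairwise, and all
#' together (full). At the local scale every model also carries the movement
#' terms (SL, lnSL, cos TA) and lnSL x start-covariate interactions; at the
#' landscape scale models contain end-point habitat terms only.
#'
#' Interaction terms are written \code{"a:b"} and expanded as products by
#' \code{\link{build_design}}.
#'
#' @param scale "rsf" (landscape) or "issa" (local)
#' @return named list of character vectors of model terms
#' @export
candidate_models <- function(scale = c("rsf", "issa")) {
  scale <- match.arg(scale)
  infra <- c(forestry = "log_dist_forestry", public = "log_dist_public",
             buildings = "log_dist_building")
  combos <- list(core = character(0),
                 forestry_roads = "forestry",
                 public_roads = "public",
                 buildings = "buildings",
                 forestry_public = c("forestry", "public"),
                 forestry_buildings = c("forestry", "buildings"),
                 public_buildings = c("public", "buildings"),
                 full = c("forestry", "public", "buildings"))
  if (scale == "rsf") {
    core <- c("clearcut", "bog", "tri", "log_dist_water")
    lapply(combos, function(cb) c(core, unname(infra[cb])))
  } else {
    core <- c("sl", "log_sl", "cos_ta", "clearcut_end", "bog_end", "tri_end",
              "log_dist_water_end", "log_sl:clearcut_start")
    lapply(combos, function(cb) {
      ext <- unlist(lapply(unname(infra[cb]), function(v)
        c(paste0(v, "_end"), paste0("log_sl:", v, "_start"))))
      c(core, ext)
    })
  }
}

#' Build a design matrix from term labels
#'
#' Plain column terms are taken from \code{data}; \code{"a:b"} terms are the
#' elementwise product of the two columns.
#'
#' @param data data frame holding the covariate columns
#' @param terms character vector of term labels
#' @return numeric matrix with one column per term
#' @export
build_design <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(data))
    if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    Reduce(`*`, lapply(parts, function(p) data[[p]]))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}
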