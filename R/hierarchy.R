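#' Construct a body hierarchy (functional body mesh)
#'
#' The functional body mesh groups markers into rigid-ish body segments
#' and arranges the segments in a parent/child tree.  Loose predictors
#' regress a marker on its group co-members (siblings) and on one
#' representative marker of the parent group, so the hierarchy decides
#' which trajectories may explain which.
#'
#' @param groups named list, group name -> character vector of marker
#'   names.  Every marker must belong to exactly one group.
#' @param parents named list or character vector, group name -> parent
#'   group name; the root group is absent or maps to `NULL`/`NA`.  Parent
#'   links must form a single tree.
#' @param representatives optional named character vector, group name ->
#'   marker fixed as that group's representative (otherwise chosen per
#'   sequence by [select_parent_representative]).
#' @return an object of class `body_hierarchy`.
#' @export
body_hierarchy <- function(groups, parents = list(), representatives = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named list")
  groups <- lapply(groups, as.character)
  all_markers <- unlist(groups, use.names = FALSE)
  dup <- all_markers[duplicated(all_markers)]
  if (length(dup))
    stop("marker(s) in more than one group: ", paste(unique(dup), collapse = ", "))
  if (any(lengths(groups) == 0)) stop("empty group in hierarchy")
  gnames <- names(groups)
  parents <- as.list(parents)
  parent <- stats::setNames(rep(NA_character_, length(gnames)), gnames)
  for (g in names(parents)) {
    p <- parents[[g]]
    if (is.null(p) || length(p) == 0 || is.na(p)) next
    if (!g %in% gnames) stop("parent entry for unknown group: ", g)
    if (!p %in% gnames) stop("unknown parent group: ", p)
    if (identical(p, g)) stop("group cannot be its own parent: ", g)
    parent[[g]] <- as.character(p)
  }
  roots <- gnames[is.na(parent)]
  if (length(roots) != 1L)
    stop("parent links must form a single tree (found ",
         length(roots), " root groups)")
  # walk up from every group; revisiting a group means a cycle
  for (g in gnames) {
    seen <- character(0)
    cur <- g
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("cycle in parent links at group: ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  if (!is.null(representatives)) {
    representatives <- unlist(representatives)
    for (g in names(representatives)) {
      if (!g %in% gnames) stop("representative for unknown group: ", g)
      if (!representatives[[g]] %in% groups[[g]])
        stop("representative of ", g, " is not one of its members")
    }
  }
  structure(list(groups = groups, parent = parent,
                 representative = representatives),
            class = "body_hierarchy")
}

#' @export
print.body_hierarchy <- function(x, ...) {
  cat(sprintf("body_hierarchy: %d groups, %d markers\n",
              length(x$groups), length(unlist(x$groups))))
  for (g in names(x$groups)) {
    p <- x$parent[[g]]
    cat(sprintf("  %s (%s): %s\n", g,
                if (is.na(p)) "root" else paste0("parent ", p),
                paste(x$groups[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Load a body hierarchy from a YAML or JSON config
#'
#' The config holds a `groups` mapping (group -> member markers), a
#' `parents` mapping (group -> parent group, root omitted) and an
#' optional `representatives` mapping.
#'
#' @param path config file; `.yaml`/`.yml` parsed with yaml, `.json`
#'   with jsonlite.
#' @return a validated [body_hierarchy].
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("hierarchy config must be YAML or JSON: ", path))
  if (is.null(cfg$groups)) stop("hierarchy config lacks `groups`")
  body_hierarchy(cfg$groups,
                 parents = if (is.null(cfg$parents)) list() else cfg$parents,
                 representatives = cfg$representatives)
}

group_of <- function(hier, marker) {
  for (g in names(hier$groups))
    if (marker %in% hier$groups[[g]]) return(g)
  stop("marker not in hierarchy: ", marker)
}

#' Select the representative marker of a group's parent
#'
#' The parent group is represented by a single marker in the loose
#' predictors: the member that moves most coherently with the child
#' group.  Coherence combines two scale-free criteria by rank sum:
#' (a) the mean cosine similarity between the candidate's frame
#' differentials and those of the child-group centroid (gradient
#' coherence), and (b) the negative standard deviation of the
#' candidate-to-centroid distance (distance constancy).  Ties are broken
#' lexicographically by marker name, so selection is deterministic.
#'
#' @param seq a [mocap_sequence].
#' @param hier a [body_hierarchy].
#' @param group group name whose parent representative is wanted.
#' @return the selected parent-group marker name.
#' @export
select_parent_representative <- function(seq, hier, group) {
  if (!group %in% names(hier$groups)) stop("unknown group: ", group)
  pg <- hier$parent[[group]]
  if (is.na(pg)) stop("group ", group, " is the root and has no parent")
  if (!is.null(hier$representative) && pg %in% names(hier$representative))
    return(hier$representative[[pg]])
  cands <- sort(hier$groups[[pg]])
  if (length(cands) == 1L) return(cands)
  members <- hier$groups[[group]]
  cen <- apply(seq$positions[, members, , drop = FALSE], c(1, 3), mean)
  dcen <- diff(cen)
  coher <- numeric(length(cands))
  dconst <- numeric(length(cands))
  for (i in seq_along(cands)) {
    xyz <- marker_xyz(seq, cands[i])
    dxyz <- diff(xyz)
    num <- rowSums(dxyz * dcen)
    den <- sqrt(rowSums(dxyz^2)) * sqrt(rowSums(dcen^2))
    cs <- ifelse(den > 0, num / den, 0)
    coher[i] <- mean(cs, na.rm = TRUE)
    coher[i] <- ifelse(is.finite(coher[i]), coher[i], 0)
    d <- sqrt(rowSums((xyz - cen)^2))
    dconst[i] <- -stats::sd(d, na.rm = TRUE)
  }
  score <- rank(coher, ties.method = "average") +
    rank(dconst, ties.method = "average")
  # candidates sorted lexicographically, which.max takes the first best
  cands[which.max(score)]
}

#' Regressor markers of a marker under a hierarchy
#'
#' Resolves the marker set a loose predictor may use: the marker's
#' siblings (group co-members) plus, for non-root groups, the parent
#' group's representative.  The marker itself is excluded.
#'
#' @inheritParams select_parent_representative
#' @param marker target marker name.
#' @return list with `regressors` (character vector, parent
#'   representative first) and `parent_rep` (name or `NA`).
#' @export
loose_regressors <- function(seq, hier, marker) {
  g <- group_of(hier, marker)
  sibs <- setdiff(hier$groups[[g]], marker)
  prep <- NA_character_
  if (!is.na(hier$parent[[g]]))
    prep <- select_parent_representative(seq, hier, g)
  regs <- c(if (!is.na(prep)) prep, sibs)
  if (length(regs) == 0)
    stop("marker ", marker, " has neither siblings nor a parent group")
  list(regressors = regs, parent_rep = prep)
}
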