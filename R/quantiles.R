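#' Score exposure concentrations into quantile bins
#'
#' Replaces each exposure column by its empirical quantile bin `0, ..., q - 1`.
#' Binning cuts the average ranks of each column at the empirical quantiles
#' `k/q` (`k = 1, ..., q - 1`); observations tied with a cut point fall in the
#' lower bin, so scores depend only on the ordering of the values and are
#' invariant to any strictly increasing transform of a column.
#'
#' @param data A data frame whose columns are exposure concentrations, or a
#'   numeric matrix. Non-numeric columns are an error; use `components` to
#'   restrict to the exposure columns.
#' @param q Number of quantile bins (quartiles `q = 4` are conventional).
#' @param components Optional character vector naming the columns to score;
#'   defaults to all columns.
#' @return A tibble of integer scores in `0:(q - 1)` with the same column
#'   names, carrying `q` as the `"q"` attribute.
#' @examples
#' score_quantiles(data.frame(x = 1:8), q = 4)
#' @export
score_quantiles <- function(data, q = 4, components = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q < 2 || q != round(q)) {
    abort("`q` must be a single integer >= 2.")
  }
  X <- as_component_matrix(data, components)
  scores <- apply(X, 2L, score_column, q = q)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(X),
                                             dimnames = list(NULL, colnames(X)))
  out <- tibble::as_tibble(as.data.frame(scores))
  attr(out, "q") <- as.integer(q)
  out
}

score_column <- function(x, q) {
  n_distinct <- length(unique(x))
  if (n_distinct < q) {
    warn(paste0("column has ", n_distinct, " distinct values for ", q,
                " bins; ties collapse bins toward the lower score"))
  }
  r <- rank(x, ties.method = "average")
  cuts <- quantile(r, probs = seq_len(q - 1L) / q, names = FALSE)
  as.integer(vapply(r, function(ri) sum(ri > cuts), numeric(1)))
}

as_component_matrix <- function(data, components = NULL) {
  if (is.matrix(data)) {
    X <- data
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  } else {
    data <- as.data.frame(data)
    if (!is.null(components)) {
      missing <- setdiff(components, names(data))
      if (length(missing)) {
        abort(paste0("components not found in data: ",
                     paste(missing, collapse = ", ")))
      }
      data <- data[components]
    }
    not_num <- names(data)[!vapply(data, is.numeric, logical(1))]
    if (length(not_num)) {
      abort(paste0("non-numeric exposure columns: ",
                   paste(not_num, collapse = ", ")))
    }
    X <- as.matrix(data)
  }
  if (anyNA(X)) abort("exposure values contain missing entries")
  if (ncol(X) < 1L) abort("need at least one exposure component")
  if (nrow(X) < 2L) abort("need at least two subjects")
  if (anyDuplicated(colnames(X))) abort("component names must be unique")
  X
}

#' Split subjects into training and validation halves
#'
#' Draws a deterministic random partition of `1:n` used to separate the
#' bootstrap weight-estimation data from the held-out validation data.
#'
#' @param n Number of subjects.
#' @param fraction Proportion assigned to the training part.
#' @param seed Integer seed making the split reproducible.
#' @return A list with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive; `length(train) == round(fraction * n)`) and the
#'   `seed` used.
#' @export
split_train_validation <- function(n, fraction = 0.5, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 4) abort("`n` must be >= 4.")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be strictly between 0 and 1.")
  }
  n_train <- round(fraction * n)
  if (n_train < 2 || n - n_train < 2) {
    abort("split leaves fewer than 2 subjects in one part")
  }
  train <- sort(with_local_seed(seed, sample.int(n, n_train)))
  list(train = train,
       validation = setdiff(seq_len(n), train),
       seed = as.integer(seed))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Define and validate the component-to-group assignment
#'
#' @param groups Either a named list of character vectors
#'   (`list(metals = c("pb", "cd"), ...)`) or a data frame with columns
#'   `component` and `group`.
#' @param data Optional exposure data (or matrix); when supplied, every
#'   component column must be assigned to exactly one group.
#' @return An object of class `"group_structure"`: a tibble with columns
#'   `component` and `group` (factor in group order), plus attributes
#'   `group_names` and `sizes`.
#' @export
group_structure <- function(groups, data = NULL) {
  if (inherits(groups, "group_structure") && is.null(data)) return(groups)
  if (is.data.frame(groups)) {
    if (!all(c("component", "group") %in% names(groups))) {
      abort("group data frame needs columns `component` and `group`")
    }
    map <- tibble::tibble(component = as.character(groups$component),
                          group = as.character(groups$group))
  } else if (is.list(groups)) {
    if (is.null(names(groups)) || any(names(groups) == "")) {
      abort("group list must be fully named")
    }
    map <- tibble::tibble(
      component = as.character(unlist(groups, use.names = FALSE)),
      group = rep(names(groups), lengths(groups))
    )
  } else {
    abort("`groups` must be a named list or a component/group data frame")
  }
  dup <- map$component[duplicated(map$component)]
  if (length(dup)) {
    abort(paste0("components assigned to more than one group: ",
                 paste(unique(dup), collapse = ", ")))
  }
  group_names <- unique(map$group)
  if (!is.null(data)) {
    comps <- colnames(as_component_matrix(data, components = NULL))
    unassigned <- setdiff(comps, map$component)
    if (length(unassigned)) {
      abort(paste0("components missing from the group assignment: ",
                   paste(unassigned, collapse = ", ")))
    }
    map <- map[map$component %in% comps, , drop = FALSE]
    group_names <- group_names[group_names %in% map$group]
  }
  sizes <- vapply(group_names, function(g) sum(map$group == g), integer(1))
  if (any(sizes < 1L)) {
    abort(paste0("empty groups: ",
                 paste(group_names[sizes < 1L], collapse = ", ")))
  }
  map$group <- factor(map$group, levels = group_names)
  structure(map,
            group_names = group_names,
            sizes = sizes,
            class = c("group_structure", class(map)))
}

#' @export
print.group_structure <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("Group structure: ", length(sizes), " group(s), ",
      nrow(x), " components (", paste(sizes, collapse = ", "), ")\n", sep = "")
  NextMethod()
}
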