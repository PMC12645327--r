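#' Construct a TraitMatrix
#'
#' @param states matrix (or data.frame) of 0/1/NA entries, taxa in rows.
#'   Character entries "0"/"1"/"?" are accepted and mapped.
#' @param taxa optional taxon labels (default: row names of \code{states}).
#' @param charIds optional character ids (default: column names, else c1..cK).
#' @param levels optional integer vector of dependency levels (1-4).
#' @param categories optional character vector of category labels.
#' @param weights positive per-character weights (default 1).
#' @return A validated \linkS4class{TraitMatrix}.
#' @examples
#' m <- TraitMatrix(rbind(A = c(1, 0), B = c(0, 1)))
#' taxa(m)
#' @export
TraitMatrix <- function(states, taxa = rownames(states),
    charIds = colnames(states), levels = NULL, categories = NULL,
    weights = NULL) {
  states <- as.matrix(states)
  force(taxa); force(charIds)   # defaults must see the original dimnames
  if (is.character(states)) {
    st <- states
    states <- matrix(NA_integer_, nrow(st), ncol(st))
    states[st == "0"] <- 0L
    states[st == "1"] <- 1L
    badMat <- !(st %in% c("0", "1", "?", "-", NA))
    dim(badMat) <- dim(st)
    bad <- which(badMat, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-binary symbol '%s' at row %d, column %d",
        st[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  } else {
    storage.mode(states) <- "integer"
  }
  if (is.null(taxa)) stop("taxon labels are required")
  if (is.null(charIds)) charIds <- paste0("c", seq_len(ncol(states)))
  dimnames(states) <- list(as.character(taxa), as.character(charIds))
  if (is.null(weights)) weights <- rep(1, ncol(states))
  obj <- new("TraitMatrix", states = states,
    levels = if (is.null(levels)) NULL else as.integer(levels),
    categories = if (is.null(categories)) NULL else as.character(categories),
    weights = as.numeric(weights))
  validObject(obj)
  obj
}

#' @rdname TraitMatrix
#' @param x a TraitMatrix.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname TraitMatrix
#' @export
setMethod("taxa", "TraitMatrix", function(x) rownames(x@states))

#' @rdname TraitMatrix
#' @export
setGeneric("charIds", function(x) standardGeneric("charIds"))
#' @rdname TraitMatrix
#' @export
setMethod("charIds", "TraitMatrix", function(x) colnames(x@states))

#' @rdname TraitMatrix
#' @export
setGeneric("traitStates", function(x) standardGeneric("traitStates"))
#' @rdname TraitMatrix
#' @export
setMethod("traitStates", "TraitMatrix", function(x) x@states)

#' @rdname TraitMatrix
#' @export
setGeneric("charLevels", function(x) standardGeneric("charLevels"))
#' @rdname TraitMatrix
#' @export
setMethod("charLevels", "TraitMatrix", function(x) x@levels)

#' @rdname TraitMatrix
#' @export
setGeneric("charCategories", function(x) standardGeneric("charCategories"))
#' @rdname TraitMatrix
#' @export
setMethod("charCategories", "TraitMatrix", function(x) x@categories)

#' @rdname TraitMatrix
#' @export
setGeneric("charWeights", function(x) standardGeneric("charWeights"))
#' @rdname TraitMatrix
#' @export
setMethod("charWeights", "TraitMatrix", function(x) x@weights)

#' Read a binary trait matrix from NEXUS or CSV
#'
#' NEXUS files must use \code{datatype=standard} with symbols 0/1 and missing
#' symbol '?'. CSV files have the taxon label in the first column, a header
#' row of character ids, and cells in \{0, 1, ?\}. An optional annotation CSV
#' with columns \code{char_id, level, category, weight} attaches per-character
#' metadata.
#'
#' @param path input file.
#' @param format "nexus" or "csv" (default guessed from the extension).
#' @param annotations optional annotation CSV path.
#' @return A \linkS4class{TraitMatrix}.
#' @export
readTraitMatrix <- function(path, format = c("guess", "nexus", "csv"),
    annotations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess")
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "csv"
  if (format == "nexus") {
    dat <- ape::read.nexus.data(path)
    if (anyDuplicated(names(dat))) stop("duplicate taxon label in NEXUS file")
    st <- do.call(rbind, lapply(dat, function(v) toupper(unlist(v))))
    rownames(st) <- names(dat)
    colnames(st) <- paste0("c", seq_len(ncol(st)))
    m <- TraitMatrix(st)
  } else {
    df <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (anyDuplicated(df[[1]])) stop("duplicate taxon label in CSV file")
    st <- as.matrix(df[, -1, drop = FALSE])
    rownames(st) <- df[[1]]
    m <- TraitMatrix(st)
  }
  if (!is.null(annotations)) m <- attachAnnotations(m, annotations)
  m
}

#' @rdname readTraitMatrix
#' @param m a TraitMatrix.
#' @export
attachAnnotations <- function(m, annotations) {
  ann <- if (is.data.frame(annotations)) annotations else
    read.csv(annotations, check.names = FALSE)
  if (!"char_id" %in% names(ann)) stop("annotation table needs a char_id column")
  unknown <- setdiff(ann$char_id, charIds(m))
  if (length(unknown) > 0)
    stop("annotation char_id not in matrix: ", paste(unknown, collapse = ", "))
  idx <- match(charIds(m), ann$char_id)
  lv <- if ("level" %in% names(ann)) as.integer(ann$level[idx]) else m@levels
  ca <- if ("category" %in% names(ann)) as.character(ann$category[idx]) else
    m@categories
  w <- if ("weight" %in% names(ann)) as.numeric(ann$weight[idx]) else m@weights
  if (!is.null(w) && anyNA(w)) w[is.na(w)] <- 1
  TraitMatrix(m@states, levels = lv, categories = ca, weights = w)
}

#' Write a trait matrix (round-trip safe)
#'
#' @param m a TraitMatrix.
#' @param path output file.
#' @param format "nexus" or "csv".
#' @param annotationPath optional path for the annotation CSV
#'   (char_id, level, category, weight).
#' @export
writeTraitMatrix <- function(m, path, format = c("csv", "nexus"),
    annotationPath = NULL) {
  format <- match.arg(format)
  st <- m@states
  ch <- matrix(as.character(st), nrow(st), ncol(st), dimnames = dimnames(st))
  ch[is.na(st)] <- "?"
  if (format == "csv") {
    df <- data.frame(taxon = rownames(ch), ch, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- split(ch, row(ch))
    names(rows) <- rownames(ch)
    ape::write.nexus.data(rows, path, format = "standard",
      datablock = FALSE, interleaved = FALSE)
  }
  if (!is.null(annotationPath)) {
    ann <- data.frame(char_id = charIds(m),
      level = if (is.null(m@levels)) NA else m@levels,
      category = if (is.null(m@categories)) NA else m@categories,
      weight = m@weights)
    write.csv(ann, annotationPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Subset characters by annotation
#'
#' Keeps the characters for which \code{selector} is TRUE; taxa and all
#' annotations are preserved. Selecting zero characters is an error, since an
#' analysis on an empty matrix is meaningless.
#'
#' @param m a TraitMatrix.
#' @param selector either a logical/integer index over characters, or a
#'   function taking the per-character annotation data.frame
#'   (char_id, level, category, weight) and returning a logical vector.
#' @return The restricted \linkS4class{TraitMatrix}.
#' @examples
#' m <- TraitMatrix(rbind(A = c(1, 0), B = c(0, 1)), levels = c(1, 2))
#' subsetCharacters(m, function(a) a$level == 1)
#' @export
subsetCharacters <- function(m, selector) {
  ann <- data.frame(char_id = charIds(m),
    level = if (is.null(m@levels)) NA_integer_ else m@levels,
    category = if (is.null(m@categories)) NA_character_ else m@categories,
    weight = m@weights, stringsAsFactors = FALSE)
  keep <- if (is.function(selector)) selector(ann) else selector
  if (is.logical(keep)) keep <- which(keep)
  if (length(keep) == 0)
    stop("empty character selection: no characters match the selector")
  TraitMatrix(m@states[, keep, drop = FALSE],
    levels = if (is.null(m@levels)) NULL else m@levels[keep],
    categories = if (is.null(m@categories)) NULL else m@categories[keep],
    weights = m@weights[keep])
}

#' Assign per-character weights by dependency level
#'
#' Sets each character's weight from its level, e.g. the inverse-dependency
#' scheme giving level 1 weight 8, level 2 weight 4, level 3 weight 2 and
#' level 4 weight 1. An integer weight w makes the likelihood identical to
#' duplicating that character w times.
#'
#' @param m an annotated TraitMatrix (levels required).
#' @param weightByLevel named numeric, mapping level -> positive weight,
#'   e.g. \code{c("1" = 8, "2" = 4, "3" = 2, "4" = 1)}.
#' @return The reweighted \linkS4class{TraitMatrix}.
#' @export
applyLevelWeights <- function(m, weightByLevel) {
  if (is.null(m@levels)) stop("matrix has no level annotations")
  key <- as.character(m@levels)
  missing <- setdiff(unique(key), names(weightByLevel))
  if (length(missing) > 0)
    stop("no weight mapping for level(s): ", paste(missing, collapse = ", "))
  TraitMatrix(m@states, levels = m@levels, categories = m@categories,
    weights = as.numeric(weightByLevel[key]))
}

#' Restrict two matrices to mapped shared taxa
#'
#' Labels may differ across datasets (e.g. a language name paired with a loom
#' name); \code{taxonMap} pairs them. Both matrices are restricted to the
#' mapped taxa and re-ordered identically by pair order.
#'
#' @param a,b TraitMatrix objects.
#' @param taxonMap two-column data.frame (or matrix) pairing labels of
#'   \code{a} (column 1) with labels of \code{b} (column 2).
#' @return list(a = ..., b = ...) of restricted matrices in matching order.
#' @export
matchSharedTaxa <- function(a, b, taxonMap) {
  taxonMap <- as.data.frame(taxonMap, stringsAsFactors = FALSE)
  if (nrow(taxonMap) == 0) stop("taxon map is empty")
  la <- as.character(taxonMap[[1]]); lb <- as.character(taxonMap[[2]])
  if (anyDuplicated(la) || anyDuplicated(lb))
    stop("duplicate pairing in taxon map")
  missA <- setdiff(la, taxa(a))
  if (length(missA) > 0)
    stop("mapped label not in first matrix: ", paste(missA, collapse = ", "))
  missB <- setdiff(lb, taxa(b))
  if (length(missB) > 0)
    stop("mapped label not in second matrix: ", paste(missB, collapse = ", "))
  sub <- function(m, labs) TraitMatrix(m@states[labs, , drop = FALSE],
    levels = m@levels, categories = m@categories, weights = m@weights)
  list(a = sub(a, la), b = sub(b, lb))
}

#' Merge two trait matrices over identical taxa (scenario-A concatenation)
#'
#' Appends the characters of \code{b} to \code{a}; categories are retained
#' (prefixed by origin) so partition labels survive concatenation.
#'
#' @param a,b TraitMatrix objects over the same taxa (same order).
#' @return The merged \linkS4class{TraitMatrix}.
#' @export
mergeTraitMatrices <- function(a, b) {
  if (!identical(taxa(a), taxa(b)))
    stop("matrices must share identical taxa in identical order")
  ids <- make.unique(c(paste0("a.", charIds(a)), paste0("b.", charIds(b))))
  st <- cbind(a@states, b@states)
  colnames(st) <- ids
  catA <- if (is.null(a@categories)) rep("a", ncol(a@states)) else
    paste0("a.", a@categories)
  catB <- if (is.null(b@categories)) rep("b", ncol(b@states)) else
    paste0("b.", b@categories)
  lv <- if (is.null(a@levels) && is.null(b@levels)) NULL else
    c(if (is.null(a@levels)) rep(1L, ncol(a@states)) else a@levels,
      if (is.null(b@levels)) rep(1L, ncol(b@states)) else b@levels)
  TraitMatrix(st, levels = lv, categories = c(catA, catB),
    weights = c(a@weights, b@weights))
}
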