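#' Construct a Pedigree
#'
#' Builds a [Pedigree-class] from parallel vectors, re-sorting so that every
#' parent precedes its offspring when the input order is not already
#' topological (the permutation is reported via `message`).  Cycles and
#' self-ancestry raise errors.
#'
#' @param id character vector of individual ids.
#' @param sire,dam parent ids; `NA` (or `"0"`/`"."` in files) = unknown.
#' @param genotyped logical vector.
#' @param role character vector, each `"training"`, `"evaluation"` or
#'   `"none"`.
#' @return a [Pedigree-class].
#' @export
Pedigree <- function(id, sire, dam, genotyped = FALSE,
                     role = "none") {
  n <- length(id)
  r <- data.frame(id = as.character(id), sire = as.character(sire),
                  dam = as.character(dam),
                  genotyped = rep_len(as.logical(genotyped), n),
                  role = rep_len(as.character(role), n),
                  stringsAsFactors = FALSE)
  r$sire[r$sire %in% c("0", ".", "")] <- NA
  r$dam[r$dam %in% c("0", ".", "")] <- NA
  if (anyDuplicated(r$id)) stop("duplicated individual ids in pedigree")
  bad <- !r$role %in% c("training", "evaluation", "none")
  if (any(bad)) stop("unknown role token: ", r$role[bad][1])
  if (any(!is.na(r$sire) & r$sire == r$id) ||
      any(!is.na(r$dam) & r$dam == r$id))
    stop("individual listed as its own parent")
  if (!isTopoSorted(r)) {
    ord <- topoOrderPedigree(r)
    message("pedigree re-sorted so parents precede offspring")
    r <- r[ord, , drop = FALSE]
    rownames(r) <- NULL
  }
  new("Pedigree", records = r)
}

isTopoSorted <- function(r) {
  pos <- seq_len(nrow(r))
  names(pos) <- r$id
  for (col in c("sire", "dam")) {
    p <- r[[col]]
    known <- !is.na(p)
    unknown <- setdiff(p[known], r$id)
    if (length(unknown))
      stop("parent not listed in pedigree: ", unknown[1])
    if (any(pos[p[known]] >= pos[known])) return(FALSE)
  }
  TRUE
}

# Kahn's algorithm; errors on cycles (which include self-ancestry chains).
topoOrderPedigree <- function(r) {
  n <- nrow(r)
  idx <- seq_len(n)
  names(idx) <- r$id
  parents <- lapply(seq_len(n), function(i) {
    p <- c(r$sire[i], r$dam[i])
    p <- p[!is.na(p)]
    unknown <- setdiff(p, r$id)
    if (length(unknown))
      stop("parent not listed in pedigree: ", unknown[1])
    unname(idx[p])
  })
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[[i]])
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    # stable: keep original file order among ready individuals
    i <- queue[1]
    queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) != n) stop("pedigree contains a parentage cycle")
  out
}

#' Read a pedigree table
#'
#' Five-column TSV (`id`, `sire`, `dam`, `genotyped` in \{0, 1\}, `role` in
#' \{training, evaluation, none\}); unknown parents coded `0` or `.`;
#' `#` comment lines ignored.  The result is topologically sorted.
#'
#' @param path file path.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "integer", "character"))
  need <- c("id", "sire", "dam", "genotyped", "role")
  if (!all(need %in% names(tab)))
    stop("pedigree file needs columns ", paste(need, collapse = ", "))
  Pedigree(tab$id, tab$sire, tab$dam, tab$genotyped == 1L, tab$role)
}

#' Write a pedigree table
#' @param x a [Pedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(x, path) {
  r <- pedRecords(x)
  out <- data.frame(id = r$id,
                    sire = ifelse(is.na(r$sire), "0", r$sire),
                    dam = ifelse(is.na(r$dam), "0", r$dam),
                    genotyped = as.integer(r$genotyped), role = r$role)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn Pedigree-class the records data.frame.
#' @param x a Pedigree.
#' @export
setMethod("pedRecords", "Pedigree", function(x) x@records)

#' @describeIn Pedigree-class ids in pedigree (topological) order.
#' @export
setMethod("individualIds", "Pedigree", function(x) x@records$id)

setMethod("show", "Pedigree", function(object) {
  r <- object@records
  founders <- sum(is.na(r$sire) & is.na(r$dam))
  cat("Pedigree:", nrow(r), "individuals (", founders, "founders ),",
      sum(r$genotyped), "genotyped\n")
  cat("  roles:", sum(r$role == "training"), "training /",
      sum(r$role == "evaluation"), "evaluation\n")
})
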