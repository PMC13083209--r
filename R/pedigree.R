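#' Read a pedigree file
#'
#' Reads a three-column pedigree (`id,sire,dam`) from CSV. Empty fields, `"0"`
#' and `"NA"` all denote an unknown parent and are normalised to `NA`.
#'
#' @param path Path to a CSV file.
#' @param header Logical; does the file have a header row? If `TRUE` the
#'   columns are matched by name (`id`, `sire`, `dam`); otherwise the first
#'   three columns are taken in that order.
#' @return A pedigree tibble (columns `id`, `sire`, `dam`, all character),
#'   validated and topologically sorted so parents precede offspring.
#' @seealso [ped_validate()], [additive_relationship()]
#' @export
read_pedigree <- function(path, header = TRUE) {
  raw <- utils::read.csv(path, header = header, colClasses = "character",
                         strip.white = TRUE)
  if (header) {
    need <- c("id", "sire", "dam")
    if (!all(need %in% names(raw))) {
      abort("pedigree file must have columns 'id', 'sire', 'dam'")
    }
    raw <- raw[need]
  } else {
    if (ncol(raw) < 3) abort("pedigree file must have at least 3 columns")
    raw <- raw[, 1:3]
    names(raw) <- c("id", "sire", "dam")
  }
  ped_validate(tibble::as_tibble(raw))
}

#' Construct a pedigree from vectors
#'
#' @param id,sire,dam Character vectors of equal length; `NA`, `""`, `"0"` and
#'   `"NA"` in `sire`/`dam` denote unknown parents.
#' @return A validated, topologically sorted pedigree tibble.
#' @export
pedigree <- function(id, sire, dam) {
  ped_validate(tibble::tibble(id = as.character(id),
                              sire = as.character(sire),
                              dam = as.character(dam)))
}

normalise_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
  x
}

#' Validate and topologically sort a pedigree
#'
#' Checks id uniqueness and acyclicity, normalises unknown-parent codes to
#' `NA`, and returns a copy ordered so that every parent precedes its
#' offspring (Kahn's algorithm). Parents that appear only in the `sire`/`dam`
#' columns are an error: every parent must have its own record (or be
#' unknown).
#'
#' @param ped A data frame with columns `id`, `sire`, `dam`.
#' @return The sorted pedigree tibble with attribute `sorted = TRUE`.
#' @export
ped_validate <- function(ped) {
  ped <- tibble::as_tibble(ped)[, c("id", "sire", "dam")]
  ped$id <- as.character(ped$id)
  ped$sire <- normalise_parent(ped$sire)
  ped$dam <- normalise_parent(ped$dam)
  if (anyNA(ped$id) || any(ped$id == "")) abort("missing individual id")
  if (anyDuplicated(ped$id)) {
    abort(paste0("duplicate pedigree id(s): ",
                 paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  }
  pars <- unique(c(ped$sire, ped$dam))
  pars <- pars[!is.na(pars)]
  missing <- setdiff(pars, ped$id)
  if (length(missing)) {
    abort(paste0("parent id(s) not declared as individuals: ",
                 paste(missing, collapse = ", ")))
  }

  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  # Kahn topological sort over parent -> offspring edges
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ped$id[indeg > 0]
    abort(paste0("pedigree contains a cycle involving: ",
                 paste(cyc, collapse = ", ")))
  }
  out <- ped[order, ]
  attr(out, "sorted") <- TRUE
  out
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Builds the full additive relationship matrix A by the tabular (recursive)
#' method: for individual o with parents s and d,
#' `A[o, x] = (A[s, x] + A[d, x]) / 2` for earlier x, and
#' `A[o, o] = 1 + A[s, d] / 2`. Unknown parents are treated as unique,
#' unrelated, non-inbred founders.
#'
#' @param ped A pedigree (validated and sorted automatically if needed).
#' @param keep Optional character vector of ids; the returned matrix is
#'   restricted to these individuals (in the given order). Ancestors still
#'   contribute through the recursion.
#' @return A dense symmetric numeric matrix with id dimnames. Diagonal
#'   entries are `1 + F` (F the inbreeding coefficient).
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' additive_relationship(ped)["o", "s"]  # 0.5
#' @export
additive_relationship <- function(ped, keep = NULL) {
  if (!isTRUE(attr(ped, "sorted"))) ped <- ped_validate(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      aij <- (as_ + ad_) / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else A[s, d] / 2
  }
  if (!is.null(keep)) {
    missing <- setdiff(keep, ped$id)
    if (length(missing)) {
      abort(paste0("unknown id(s) in keep: ", paste(missing, collapse = ", ")))
    }
    A <- A[keep, keep, drop = FALSE]
  }
  A
}

#' Monte-Carlo additive relationships by gene dropping
#'
#' Independent oracle for [additive_relationship()]: founder alleles are
#' labelled uniquely and dropped through the pedigree by Mendelian sampling;
#' the empirical relationship is twice the identity-by-descent kinship,
#' averaged over replicates.
#'
#' @param ped A pedigree.
#' @param n_rep Number of independent gene-dropping replicates.
#' @param seed Integer seed.
#' @return A list with `A` (empirical relationship matrix) and `se`
#'   (per-entry Monte-Carlo standard errors).
#' @export
additive_relationship_mc <- function(ped, n_rep = 1e5, seed = 1) {
  if (!isTRUE(attr(ped, "sorted"))) ped <- ped_validate(ped)
  set.seed(seed)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  a1 <- matrix(0L, n, n_rep)
  a2 <- matrix(0L, n, n_rep)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      a1[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
    }
    if (is.na(di[i])) {
      a2[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_rep) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- A
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
        (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      # relationship = 2 * kinship = mean(s) / 2
      A[i, j] <- A[j, i] <- mean(s) / 2
      SE[i, j] <- SE[j, i] <- sd(s) / 2 / sqrt(n_rep)
    }
  }
  list(A = A, se = SE)
}

#' Write a pedigree to CSV
#' @param ped A pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
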