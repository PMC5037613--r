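#' Pedigree objects
#'
#' A pedigree is stored as a data frame with one row per individual and
#' columns `id`, `father`, `mother` (`NA` for founders), `sex`
#' (`"male"`, `"female"`, `"unknown"`) and `affected` (`"yes"`, `"no"`,
#' `"unknown"`), carrying the family name as an attribute.  Construction
#' validates the structure: parent references must resolve or be `NA`,
#' every non-founder needs both parents, parent sexes must be consistent,
#' and the parent graph must be acyclic.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother identifiers of the parents (`NA` for founders).
#' @param sex `"male"`, `"female"` or `"unknown"` per individual.
#' @param affected `"yes"`, `"no"` or `"unknown"` per individual.
#' @param name single string naming the family.
#'
#' @return An object of class `pedigree` (a validated data frame).
#' @examples
#' trio <- pedigree(
#'   id = c("F", "M", "C"),
#'   father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
#'   sex = c("male", "female", "female"),
#'   affected = c("no", "no", "yes")
#' )
#' founders(trio)
#' @export
pedigree <- function(id, father, mother, sex, affected, name = "FAM1") {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  sex <- match.arg(as.character(sex), c("male", "female", "unknown"),
                   several.ok = TRUE)
  affected <- match.arg(as.character(affected), c("yes", "no", "unknown"),
                        several.ok = TRUE)
  n <- length(id)
  stopifnot(length(father) == n, length(mother) == n,
            length(sex) == n, length(affected) == n)
  if (anyDuplicated(id)) {
    stop("duplicated individual ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  ped <- data.frame(id = id, father = father, mother = mother,
                    sex = sex, affected = affected,
                    stringsAsFactors = FALSE)
  attr(ped, "name") <- as.character(name)[1]
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname pedigree
#' @param ped a `pedigree` object.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  has_f <- !is.na(ped$father)
  has_m <- !is.na(ped$mother)
  if (any(has_f != has_m)) {
    stop("individuals with exactly one parent: ",
         paste(ped$id[has_f != has_m], collapse = ", "))
  }
  bad <- setdiff(c(ped$father[has_f], ped$mother[has_m]), ped$id)
  if (length(bad)) {
    stop("unresolved parent references: ", paste(bad, collapse = ", "))
  }
  fs <- ped$sex[match(ped$father[has_f], ped$id)]
  ms <- ped$sex[match(ped$mother[has_m], ped$id)]
  if (any(fs == "female") || any(ms == "male")) {
    stop("parent sex inconsistent with father/mother role")
  }
  if (is.null(pedigree_depth(ped))) {
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  }
  invisible(ped)
}

# Generation depth per individual (founders = 0); NULL if the parent graph
# has a cycle.  Also the basis for topological ordering.
pedigree_depth <- function(ped) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  depth <- ifelse(is.na(fi), 0L, NA_integer_)
  for (iter in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) return(depth)
    for (i in todo) {
      df <- depth[fi[i]]; dm <- depth[mi[i]]
      if (!is.na(df) && !is.na(dm)) depth[i] <- pmax(df, dm) + 1L
    }
  }
  NULL
}

#' @rdname pedigree
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[is.na(ped$father)]
}

#' @rdname pedigree
#' @export
affected_ids <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[ped$affected == "yes"]
}

#' @rdname pedigree
#' @export
unaffected_ids <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[ped$affected == "no"]
}

#' Number of meioses in a pedigree
#'
#' Two per non-founder: one paternal, one maternal.
#' @param ped a `pedigree` object.
#' @return integer count of meioses.
#' @export
n_meioses <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  2L * sum(!is.na(ped$father))
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d individuals (%d founders, %d affected)\n",
              attr(x, "name"), nrow(x), length(founders(x)),
              sum(x$affected == "yes")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Kinship and inbreeding coefficients
#'
#' Recursive computation of the kinship matrix phi over all pedigree
#' members (phi\[i,j\] = probability that one allele drawn at random from i
#' and one from j are identical by descent).  The inbreeding coefficient
#' of an individual is the kinship of its parents.
#'
#' @param ped a `pedigree` object.
#' @return `kinship_matrix()`: a symmetric numeric matrix with individual
#'   ids as dimnames. `inbreeding()`: a named numeric vector.
#' @examples
#' # child of first cousins has F = 1/16
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ord <- order(pedigree_depth(ped))
  ids <- ped$id[ord]
  fi <- match(ped$father[ord], ids)
  mi <- match(ped$mother[ord], ids)
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fi[i], mi[i]])
    }
    for (j in seq_len(i - 1L)) {
      # j precedes i, so i's parents are already filled in rows <= i
      phi[i, j] <- phi[j, i] <-
        if (is.na(fi[i])) 0 else 0.5 * (phi[j, fi[i]] + phi[j, mi[i]])
    }
  }
  phi[ped$id, ped$id]
}

#' @rdname kinship_matrix
#' @export
inbreeding <- function(ped) {
  phi <- kinship_matrix(ped)
  out <- 2 * diag(phi) - 1
  names(out) <- colnames(phi)
  out
}

#' Read and write 6-column PED files
#'
#' The classic linkage PED layout: family, individual, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), affection (2 = affected,
#' 1 = unaffected, 0 = unknown), tab-separated, `0` for missing parents.
#'
#' @param path file path.
#' @param ped a `pedigree` object.
#' @return `read_ped()` returns a `pedigree`; `write_ped()` returns the
#'   path invisibly.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 6) stop("PED file must have 6 columns")
  sex <- c(`1` = "male", `2` = "female", `0` = "unknown")[tab[[5]]]
  aff <- c(`2` = "yes", `1` = "no", `0` = "unknown")[tab[[6]]]
  pedigree(id = tab[[2]],
           father = ifelse(tab[[3]] == "0", NA, tab[[3]]),
           mother = ifelse(tab[[4]] == "0", NA, tab[[4]]),
           sex = unname(sex), affected = unname(aff),
           name = tab[[1]][1])
}

#' @rdname read_ped
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  tab <- data.frame(
    family = attr(ped, "name"),
    id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = c(male = "1", female = "2", unknown = "0")[ped$sex],
    affected = c(yes = "2", no = "1", unknown = "0")[ped$affected]
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reconstructed study pedigree
#'
#' A synthetic reconstruction of the extended consanguineous family in
#' which the recessive neuropsychiatric syndrome was mapped: five
#' affected girls in three sibships — three affected sisters (V:1, V:2,
#' V:3), their affected first cousin (IV:1), and an affected more distant
#' (second) cousin (IV:6) — with consanguineous parental unions
#' throughout.  The published family figure is not machine-readable, so
#' this topology is a reconstruction from the textual family description:
#' two founding couples whose children intermarry, making each affected
#' child's parents double first cousins.  All analyses in this package
#' treat it as a synthetic stand-in, not as the family's true structure.
#'
#' @return A `pedigree` with 26 members, 5 affected.
#' @examples
#' ped <- study_pedigree()
#' round(inbreeding(ped)[affected_ids(ped)], 3)  # 1/8 for all five
#' @export
study_pedigree <- function() {
  pedigree(
    id = c("I:1", "I:2", "I:3", "I:4",
           "II:1", "II:2", "II:5", "II:7",      # children of I:1 x I:2
           "II:3", "II:4", "II:6", "II:8",      # children of I:3 x I:4
           "III:1", "III:3",                    # children of II:1 x II:3
           "III:2", "III:4",                    # children of II:2 x II:4
           "III:5",                             # child of II:6 x II:5
           "III:6",                             # child of II:8 x II:7
           "V:1", "V:2", "V:3", "V:4",          # children of III:1 x III:2
           "IV:1", "IV:2",                      # children of III:3 x III:4
           "IV:6", "IV:7"),                     # children of III:5 x III:6
    father = c(NA, NA, NA, NA,
               "I:1", "I:1", "I:1", "I:1",
               "I:3", "I:3", "I:3", "I:3",
               "II:1", "II:1", "II:2", "II:2", "II:6", "II:8",
               "III:1", "III:1", "III:1", "III:1",
               "III:3", "III:3", "III:5", "III:5"),
    mother = c(NA, NA, NA, NA,
               "I:2", "I:2", "I:2", "I:2",
               "I:4", "I:4", "I:4", "I:4",
               "II:3", "II:3", "II:4", "II:4", "II:5", "II:7",
               "III:2", "III:2", "III:2", "III:2",
               "III:4", "III:4", "III:6", "III:6"),
    sex = c("male", "female", "male", "female",
            "male", "male", "female", "female",
            "female", "female", "male", "male",
            "male", "male", "female", "female", "male", "female",
            "female", "female", "female", "male",
            "female", "male", "female", "female"),
    affected = c(rep("no", 18),
                 "yes", "yes", "yes", "no",
                 "yes", "no",
                 "yes", "no"),
    name = "STUDYFAM-RECONSTRUCTION"
  )
}
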