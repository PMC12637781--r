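#' Construct a pedigree
#'
#' A pedigree is a validated data frame with one row per individual and
#' columns `id`, `family_id`, `father_id`, `mother_id`, `sex`
#' (`"male"`, `"female"`, `"unknown"`) and `affected` (`"affected"`,
#' `"unaffected"`, `"unknown"`). Founders have `NA` parents. A single known
#' parent is allowed: the missing one is treated as an anonymous unrelated
#' founder, which keeps partial pedigrees usable.
#'
#' Validation enforces unique ids, existing parents, sex consistent with the
#' parental role, and acyclicity (a topological order must exist).
#'
#' @param df data frame with the columns above (`father_id`/`mother_id` may
#'   use `NA` or `"0"` for founder).
#' @return a `pedigree` object (data frame subclass).
#' @export
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("F", "M", "C"), family_id = "fam1",
#'   father_id = c(NA, NA, "F"), mother_id = c(NA, NA, "M"),
#'   sex = c("male", "female", "female"),
#'   affected = c("unaffected", "unaffected", "affected")))
#' kinship_coefficient(ped, "F", "C")
pedigree <- function(df) {
  need <- c("id", "family_id", "father_id", "mother_id", "sex", "affected")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in need) df[[col]] <- as.character(df[[col]])
  df$father_id[df$father_id %in% c("0", "")] <- NA_character_
  df$mother_id[df$mother_id %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id))
    stop("duplicate individual id in pedigree: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$sex %in% c("male", "female", "unknown")))
    stop("sex must be male/female/unknown")
  if (!all(df$affected %in% c("affected", "unaffected", "unknown")))
    stop("affected must be affected/unaffected/unknown")
  for (p in c("father_id", "mother_id")) {
    known <- !is.na(df[[p]])
    missing_parent <- !(df[[p]][known] %in% df$id)
    if (any(missing_parent))
      stop("named parent not in pedigree: ",
           paste(df[[p]][known][missing_parent], collapse = ", "))
  }
  sex_of <- stats::setNames(df$sex, df$id)
  bad_f <- !is.na(df$father_id) & sex_of[df$father_id] == "female"
  bad_m <- !is.na(df$mother_id) & sex_of[df$mother_id] == "male"
  if (any(bad_f, na.rm = TRUE)) stop("father with female sex")
  if (any(bad_m, na.rm = TRUE)) stop("mother with male sex")
  # fill unknown parental sex from role
  df$sex[df$id %in% df$father_id & df$sex == "unknown"] <- "male"
  df$sex[df$id %in% df$mother_id & df$sex == "unknown"] <- "female"
  ord <- .topological_order(df)   # errors on cycles
  attr(df, "topo_order") <- ord
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn's algorithm; error if a cycle prevents a full order.
.topological_order <- function(df) {
  ids <- df$id
  idx <- stats::setNames(seq_along(ids), ids)
  parents <- lapply(seq_along(ids), function(i) {
    p <- c(df$father_id[i], df$mother_id[i])
    idx[p[!is.na(p)]]
  })
  n_unmet <- vapply(parents, length, 1L)
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) for (p in parents[[i]])
    children[[p]] <- c(children[[p]], i)
  queue <- which(n_unmet == 0L)
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      n_unmet[ch] <- n_unmet[ch] - 1L
      if (n_unmet[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids))
    stop("pedigree parentage contains a cycle (individual is its own ancestor)")
  ids[out]
}

#' Founders of a pedigree
#' @param ped a [pedigree()].
#' @return character vector of ids with both parents unknown.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]
}

#' Kinship coefficient between two pedigree members
#'
#' The kinship coefficient phi(i, j) is the probability that one allele drawn
#' at random from i and one from j are identical by descent. Computed by the
#' standard recursion with founders assumed non-inbred and mutually
#' unrelated: phi(i, i) = (1 + F_i) / 2 and, descending the individual that
#' appears later in a topological order,
#' phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2.
#' An unknown single parent is treated as an anonymous unrelated founder
#' (contributing kinship 0). Results are memoized on unordered pairs, making
#' deep consanguinity loops tractable; memoization does not change values.
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @return phi(i, j) in \[0, 1\].
#' @export
#' @examples
#' ped <- ped_first_cousin()
#' inbreeding_coefficient(ped, "c1")  # 1/16
kinship_coefficient <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  for (x in c(i, j)) if (!x %in% ped$id) stop("unknown individual id: ", x)
  depth <- stats::setNames(seq_along(attr(ped, "topo_order")),
                           attr(ped, "topo_order"))
  father <- stats::setNames(ped$father_id, ped$id)
  mother <- stats::setNames(ped$mother_id, ped$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      fa <- father[[a]]; mo <- mother[[a]]
      f_a <- if (is.na(fa) || is.na(mo)) 0 else phi(fa, mo)
      (1 + f_a) / 2
    } else {
      # descend the individual later in topological order
      if (depth[[a]] < depth[[b]]) { tmp <- a; a <- b; b <- tmp }
      fa <- father[[a]]; mo <- mother[[a]]
      if (is.na(fa) && is.na(mo)) 0
      else ((if (is.na(fa)) 0 else phi(fa, b)) +
            (if (is.na(mo)) 0 else phi(mo, b))) / 2
    }
    memo[[key]] <- val
    val
  }
  phi(i, j)
}

#' Inbreeding coefficient of a pedigree member
#'
#' F_i is the kinship of i's parents: the probability that a random autosomal
#' locus in i is autozygous. Founders and children of unrelated parents have
#' F = 0.
#'
#' @inheritParams kinship_coefficient
#' @return F in \[0, 1\].
#' @export
inbreeding_coefficient <- function(ped, i) {
  stopifnot(inherits(ped, "pedigree"))
  if (!i %in% ped$id) stop("unknown individual id: ", i)
  fa <- ped$father_id[ped$id == i]
  mo <- ped$mother_id[ped$id == i]
  if (is.na(fa) || is.na(mo)) return(0)
  kinship_coefficient(ped, fa, mo)
}

# ---- pedigree templates -----------------------------------------------------

.ped_row <- function(id, fa = NA, mo = NA, sex = "unknown",
                     aff = "unknown", fam = "fam1") {
  data.frame(id = id, family_id = fam, father_id = fa, mother_id = mo,
             sex = sex, affected = aff, stringsAsFactors = FALSE)
}

.ped_children <- function(fa, mo, n_affected, n_unaffected, fam,
                          prefix = "c") {
  n <- n_affected + n_unaffected
  if (n == 0) return(NULL)
  sexes <- rep(c("male", "female"), length.out = n)
  do.call(rbind, lapply(seq_len(n), function(k) {
    .ped_row(paste0(prefix, k), fa, mo, sexes[k],
             if (k <= n_affected) "affected" else "unaffected", fam)
  }))
}

#' Pedigree templates for consanguineous unions
#'
#' Ready-made family structures used by the simulator: a first-cousin union
#' (offspring F = 1/16), a double-first-cousin union (F = 1/8), an avuncular
#' union (F = 1/8) and an outbred trio (F = 0). Affected children are listed
#' first (`c1`, `c2`, ...), followed by unaffected siblings.
#'
#' @param n_affected,n_unaffected numbers of affected / unaffected children.
#' @param family_id family label.
#' @return a [pedigree()]; the parents of the children are always `p1`
#'   (father) and `p2` (mother).
#' @name ped_templates
NULL

#' @rdname ped_templates
#' @export
ped_first_cousin <- function(n_affected = 2, n_unaffected = 1,
                             family_id = "fam1") {
  base <- rbind(
    .ped_row("gf", sex = "male", fam = family_id),
    .ped_row("gm", sex = "female", fam = family_id),
    .ped_row("u1", "gf", "gm", "male", fam = family_id),
    .ped_row("u2", "gf", "gm", "female", fam = family_id),
    .ped_row("s1", sex = "female", fam = family_id),
    .ped_row("s2", sex = "male", fam = family_id),
    .ped_row("p1", "u1", "s1", "male", "unaffected", family_id),
    .ped_row("p2", "s2", "u2", "female", "unaffected", family_id)
  )
  pedigree(rbind(base, .ped_children("p1", "p2", n_affected, n_unaffected,
                                     family_id)))
}

#' @rdname ped_templates
#' @export
ped_double_first_cousin <- function(n_affected = 2, n_unaffected = 1,
                                    family_id = "fam1") {
  base <- rbind(
    .ped_row("ga", sex = "male", fam = family_id),
    .ped_row("gb", sex = "female", fam = family_id),
    .ped_row("gc", sex = "male", fam = family_id),
    .ped_row("gd", sex = "female", fam = family_id),
    .ped_row("a1", "ga", "gb", "male", fam = family_id),
    .ped_row("a2", "ga", "gb", "female", fam = family_id),
    .ped_row("b1", "gc", "gd", "female", fam = family_id),
    .ped_row("b2", "gc", "gd", "male", fam = family_id),
    .ped_row("p1", "a1", "b1", "male", "unaffected", family_id),
    .ped_row("p2", "b2", "a2", "female", "unaffected", family_id)
  )
  pedigree(rbind(base, .ped_children("p1", "p2", n_affected, n_unaffected,
                                     family_id)))
}

#' @rdname ped_templates
#' @export
ped_avuncular <- function(n_affected = 2, n_unaffected = 1,
                          family_id = "fam1") {
  base <- rbind(
    .ped_row("gf", sex = "male", fam = family_id),
    .ped_row("gm", sex = "female", fam = family_id),
    .ped_row("p1", "gf", "gm", "male", "unaffected", family_id),  # uncle
    .ped_row("s1", "gf", "gm", "female", fam = family_id),
    .ped_row("s2", sex = "male", fam = family_id),
    .ped_row("p2", "s2", "s1", "female", "unaffected", family_id) # niece
  )
  pedigree(rbind(base, .ped_children("p1", "p2", n_affected, n_unaffected,
                                     family_id)))
}

#' @rdname ped_templates
#' @export
ped_trio <- function(n_affected = 1, n_unaffected = 0, family_id = "fam1") {
  base <- rbind(
    .ped_row("p1", sex = "male", aff = "unaffected", fam = family_id),
    .ped_row("p2", sex = "female", aff = "unaffected", fam = family_id)
  )
  pedigree(rbind(base, .ped_children("p1", "p2", n_affected, n_unaffected,
                                     family_id)))
}

.ped_template <- function(template, n_affected, n_unaffected, family_id) {
  switch(template,
         first_cousin = ped_first_cousin(n_affected, n_unaffected, family_id),
         double_first_cousin = ped_double_first_cousin(n_affected,
                                                       n_unaffected,
                                                       family_id),
         avuncular = ped_avuncular(n_affected, n_unaffected, family_id),
         unrelated_trio = ped_trio(n_affected, n_unaffected, family_id),
         stop("unknown pedigree template: ", template))
}

#' Children of the focal couple, by affected status
#'
#' Convenience accessors used throughout: children are individuals whose both
#' parents are in the pedigree and who are nobody's parent is irrelevant —
#' here simply all individuals with the given affected status among those
#' with two named parents whose parents are each other's partners most
#' recently added. For template pedigrees the affected children are
#' `c1..ck`.
#'
#' @param ped a [pedigree()].
#' @return character vector of ids.
#' @export
affected_ids <- function(ped) ped$id[ped$affected == "affected"]

#' @rdname affected_ids
#' @export
unaffected_sib_ids <- function(ped) {
  aff <- affected_ids(ped)
  if (!length(aff)) return(character(0))
  fa <- ped$father_id[ped$id == aff[1]]
  mo <- ped$mother_id[ped$id == aff[1]]
  ped$id[!is.na(ped$father_id) & !is.na(ped$mother_id) &
           ped$father_id == fa & ped$mother_id == mo &
           ped$affected == "unaffected"]
}
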