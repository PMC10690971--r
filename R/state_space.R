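#' Health-state space for the post-AMI Markov cohort model
#'
#' Enumerates the mutually exclusive health states of the model and the
#' legal transition topology among them.  A living state is identified by
#' an event history -- how many myocardial infarctions (MI) and how many
#' strokes the patient has survived, each counted as 0, 1 or "2+" -- and a
#' phase: `chronic` (post-event maintenance), `acute_MI` or `acute_stroke`
#' (the one-year tunnel following a new non-fatal event).  Histories deeper
#' than two events of a type collapse onto the 2+ level.  States combining
#' an MI history with a stroke history are the composite states that
#' preserve the memory of both prior events.  Two absorbing death states
#' (cardiovascular and non-cardiovascular) complete the space.
#'
#' Revascularization is deliberately *not* a health state: it is a costed
#' procedure attached to cycles (see [run_cohort()]).
#'
#' @param composites Character flag, `"full"` (default) keeps every
#'   acute-over-post combination including the 2+ variants; `"minimal"`
#'   drops the acute-over-post 2+ combinations, collapsing them onto the
#'   corresponding pure acute 2+ states.  The exact composite set shown in
#'   model diagrams of this family varies between publications, so it is
#'   configurable.
#' @return An object of class `state_space`: a data frame with one row per
#'   state and columns `name`, `category`, `mi` (0/1/2 = 2+), `stroke`,
#'   `phase`, `tunnel` (logical), `absorbing` (logical), `components`
#'   (list of primitive history labels).
#' @examples
#' sp <- build_state_space()
#' sp$name
#' subset(sp, tunnel)$name
#' @export
build_state_space <- function(composites = c("full", "minimal")) {
  composites <- match.arg(composites)
  rows <- list()
  add <- function(name, category, mi, stroke, phase, tunnel, absorbing,
                  components) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, category = category, mi = mi, stroke = stroke,
      phase = phase, tunnel = tunnel, absorbing = absorbing,
      stringsAsFactors = FALSE
    )
    attr(rows[[length(rows)]], "components") <<- components
  }

  hist_label <- function(mi, stroke, phase) {
    # primitive history labels of the components making up a state
    comp <- character(0)
    if (phase == "acute_MI") {
      comp <- c(comp, if (mi >= 2) "acute_MI_2plus" else "acute_MI")
      if (stroke == 1) comp <- c(comp, "post_stroke")
      if (stroke >= 2) comp <- c(comp, "post_stroke_2plus")
    } else if (phase == "acute_stroke") {
      comp <- c(comp, if (stroke >= 2) "acute_stroke_2plus" else "acute_stroke")
      if (mi == 1) comp <- c(comp, "post_MI")
      if (mi >= 2) comp <- c(comp, "post_MI_2plus")
    } else {
      if (mi == 1) comp <- c(comp, "post_MI")
      if (mi >= 2) comp <- c(comp, "post_MI_2plus")
      if (stroke == 1) comp <- c(comp, "post_stroke")
      if (stroke >= 2) comp <- c(comp, "post_stroke_2plus")
    }
    comp
  }

  name_of <- function(mi, stroke, phase) {
    mi_tag <- c("", "Post-MI", "Post-MI 2+")[mi + 1L]
    st_tag <- c("", "Post-stroke", "Post-stroke 2+")[stroke + 1L]
    if (phase == "chronic") {
      paste(c(mi_tag, st_tag)[c(mi_tag, st_tag) != ""], collapse = " + ")
    } else if (phase == "acute_MI") {
      acute <- if (mi >= 2) "Non-fatal MI 2+" else "Non-fatal MI"
      paste(c(acute, st_tag)[c(acute, st_tag) != ""], collapse = " + ")
    } else {
      acute <- if (stroke >= 2) "Non-fatal stroke 2+" else "Non-fatal stroke"
      paste(c(acute, mi_tag)[c(acute, mi_tag) != ""], collapse = " + ")
    }
  }

  for (mi in 0:2) {
    for (stroke in 0:2) {
      if (mi == 0L && stroke == 0L) next
      composite <- mi > 0L && stroke > 0L
      cat_chronic <- if (composite) "composite"
        else if (mi == 1L) "post_MI" else if (mi == 2L) "post_MI"
        else "post_stroke"
      add(name_of(mi, stroke, "chronic"), cat_chronic, mi, stroke, "chronic",
          tunnel = FALSE, absorbing = FALSE,
          components = hist_label(mi, stroke, "chronic"))
      if (mi > 0L) {
        if (!(composites == "minimal" && composite && mi >= 2L)) {
          cat_a <- if (composite) "composite"
            else if (mi >= 2L) "acute_MI_2plus" else "acute_MI"
          add(name_of(mi, stroke, "acute_MI"), cat_a, mi, stroke, "acute_MI",
              tunnel = TRUE, absorbing = FALSE,
              components = hist_label(mi, stroke, "acute_MI"))
        }
      }
      if (stroke > 0L) {
        if (!(composites == "minimal" && composite && stroke >= 2L)) {
          cat_a <- if (composite) "composite"
            else if (stroke >= 2L) "acute_stroke_2plus" else "acute_stroke"
          add(name_of(mi, stroke, "acute_stroke"), cat_a, mi, stroke,
              "acute_stroke", tunnel = TRUE, absorbing = FALSE,
              components = hist_label(mi, stroke, "acute_stroke"))
        }
      }
    }
  }
  add("CV death", "CV_death", NA_integer_, NA_integer_, "death",
      tunnel = FALSE, absorbing = TRUE, components = "CV_death")
  add("Non-CV death", "nonCV_death", NA_integer_, NA_integer_, "death",
      tunnel = FALSE, absorbing = TRUE, components = "nonCV_death")

  comps <- lapply(rows, attr, "components")
  out <- do.call(rbind, rows)
  out$components <- comps
  rownames(out) <- NULL
  class(out) <- c("state_space", "data.frame")
  attr(out, "topology") <- space_topology(out)
  out
}

# destination indices per state, cached on the space so per-cycle matrix
# assembly is vectorized: where a new MI / new stroke / the no-event
# residual sends each living state
space_topology <- function(space) {
  n <- nrow(space)
  # when a composite tunnel is absent (minimal composite set) the event
  # collapses onto the pure acute 2+ state, dropping the cross-history
  find <- function(mi, stroke, phase) {
    i <- which(!space$absorbing & space$mi == mi & space$stroke == stroke &
                 space$phase == phase)
    if (length(i) == 1L) return(i)
    j <- if (phase == "acute_MI")
      which(!space$absorbing & space$mi == mi & space$stroke == 0L &
              space$phase == phase)
    else which(!space$absorbing & space$mi == 0L & space$stroke == stroke &
                 space$phase == phase)
    if (length(j) != 1L) stop("no state with mi=", mi, " stroke=", stroke,
                              " phase=", phase)
    j
  }
  dest_mi <- dest_stroke <- dest_chronic <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (space$absorbing[i]) next
    mi <- space$mi[i]; stroke <- space$stroke[i]; phase <- space$phase[i]
    # same-type re-events from 2+ tunnel states are suppressed (they
    # would self-loop and break the strict one-cycle tunnel)
    if (!(phase == "acute_MI" && mi >= 2L))
      dest_mi[i] <- find(min(mi + 1L, 2L), stroke, "acute_MI")
    if (!(phase == "acute_stroke" && stroke >= 2L))
      dest_stroke[i] <- find(mi, min(stroke + 1L, 2L), "acute_stroke")
    dest_chronic[i] <- state_at(space, mi, stroke, "chronic")
  }
  list(dest_mi = dest_mi, dest_stroke = dest_stroke,
       dest_chronic = dest_chronic,
       i_cv = match("CV death", space$name),
       i_ncv = match("Non-CV death", space$name))
}

#' @export
print.state_space <- function(x, ...) {
  cat("Health-state space:", nrow(x), "states (",
      sum(x$tunnel), "tunnel,", sum(x$absorbing), "absorbing )\n")
  print(as.data.frame(x[, c("name", "category", "phase", "tunnel")]), ...)
  invisible(x)
}

state_index <- function(space, name) {
  i <- match(name, space$name)
  if (anyNA(i)) stop("unknown state name(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  i
}

# index of a living state from its history/phase coordinates
state_at <- function(space, mi, stroke, phase) {
  i <- which(!space$absorbing & space$mi == mi & space$stroke == stroke &
               space$phase == phase)
  if (length(i) != 1L) stop("no state with mi=", mi, " stroke=", stroke,
                            " phase=", phase)
  i
}

#' Compose two primitive event histories into a composite health state
#'
#' Composite states preserve the memory of previous cardiovascular
#' events.  Composition is unordered: `compose_state(a, b)` and
#' `compose_state(b, a)` name the same state.  Death states are absorbing
#' and can never be part of a composite; composing two acute histories is
#' also rejected (a patient is in at most one acute tunnel at a time).
#'
#' @param space A `state_space` from [build_state_space()].
#' @param history_a,history_b Primitive history labels, e.g. `"post_MI"`,
#'   `"post_stroke_2plus"`, `"acute_MI"`, `"acute_stroke_2plus"`.
#' @return The name of the composite state in `space`.
#' @examples
#' sp <- build_state_space()
#' compose_state(sp, "post_MI", "post_stroke")
#' compose_state(sp, "acute_stroke", "post_MI")
#' @export
compose_state <- function(space, history_a, history_b) {
  prim <- c("post_MI", "post_MI_2plus", "post_stroke", "post_stroke_2plus",
            "acute_MI", "acute_MI_2plus", "acute_stroke", "acute_stroke_2plus")
  death <- c("CV_death", "nonCV_death")
  for (h in c(history_a, history_b)) {
    if (h %in% death)
      stop("cannot compose with a death state: death is absorbing")
    if (!h %in% prim) stop("unknown primitive history: ", h)
  }
  if (identical(history_a, history_b))
    stop("component histories must be distinct")
  pair <- c(history_a, history_b)
  acute <- grepl("^acute", pair)
  if (all(acute)) stop("cannot compose two acute histories")
  mi_of <- function(h) switch(h, post_MI = 1L, acute_MI = 1L,
                              post_MI_2plus = 2L, acute_MI_2plus = 2L, 0L)
  st_of <- function(h) switch(h, post_stroke = 1L, acute_stroke = 1L,
                              post_stroke_2plus = 2L, acute_stroke_2plus = 2L,
                              0L)
  mi <- max(vapply(pair, mi_of, integer(1)))
  stroke <- max(vapply(pair, st_of, integer(1)))
  if (mi == 0L || stroke == 0L)
    stop("components must carry distinct event types (one MI, one stroke)")
  phase <- if (any(acute)) {
    if (grepl("MI", pair[acute])) "acute_MI" else "acute_stroke"
  } else "chronic"
  space$name[state_at(space, mi, stroke, phase)]
}

#' Build the per-cycle transition matrix
#'
#' Assembles a row-stochastic transition matrix from per-state event
#' probabilities and death probabilities, respecting the model topology:
#' a new MI or stroke always routes through the corresponding acute tunnel
#' state, tunnel states empty into their chronic successor, death states
#' are absorbing.  Within a cycle death claims priority: if the competing
#' probabilities of a row exceed one, the non-fatal event probabilities
#' are rescaled proportionally so the row sums to one; the residual mass
#' stays in (or, for tunnel states, moves to) the appropriate post-event
#' state.
#'
#' @param space A `state_space`.
#' @param p_mi,p_stroke Numeric vectors (length = number of states) of
#'   per-cycle probabilities of a new non-fatal MI / stroke from each
#'   state.  Values for death states are ignored.
#' @param p_cv,p_ncv Per-state probabilities of cardiovascular and
#'   non-cardiovascular death within the cycle.
#' @return A `nstates x nstates` matrix with `dimnames` the state names;
#'   every row sums to 1 within 1e-12.
#' @export
build_transition_matrix <- function(space, p_mi, p_stroke, p_cv, p_ncv) {
  n <- nrow(space)
  for (v in list(p_mi = p_mi, p_stroke = p_stroke, p_cv = p_cv,
                 p_ncv = p_ncv)) {
    if (length(v) != n) stop("probability vectors must have length ", n)
  }
  probs <- cbind(p_mi, p_stroke, p_cv, p_ncv)
  if (any(probs < 0, na.rm = TRUE)) {
    bad <- space$name[which(rowSums(probs < 0) > 0)[1]]
    stop("negative probability for state '", bad, "'")
  }
  if (any(probs > 1, na.rm = TRUE)) {
    bad <- space$name[which(rowSums(probs > 1) > 0)[1]]
    stop("probability above 1 for state '", bad, "'")
  }
  topo <- attr(space, "topology")
  if (is.null(topo)) topo <- space_topology(space)
  live <- which(!space$absorbing)
  pmi <- p_mi; pst <- p_stroke
  # same-type re-events from 2+ tunnel states are suppressed (no tunnel
  # self-loops); their destination index is NA in the topology
  pmi[is.na(topo$dest_mi)] <- 0
  pst[is.na(topo$dest_stroke)] <- 0
  pd <- p_cv + p_ncv
  scl_d <- ifelse(pd > 1, 1 / pd, 1)
  pd <- pmin(pd, 1)
  pe <- pmi + pst
  scl_e <- ifelse(pe > 0 & pe > 1 - pd, (1 - pd) / pe, 1)
  pmi <- pmi * scl_e; pst <- pst * scl_e
  M <- matrix(0, n, n, dimnames = list(space$name, space$name))
  M[cbind(live, topo$i_cv)] <- (p_cv * scl_d)[live]
  M[cbind(live, topo$i_ncv)] <- M[cbind(live, topo$i_ncv)] +
    (p_ncv * scl_d)[live]
  for (i in live) {
    if (pmi[i] > 0) M[i, topo$dest_mi[i]] <- M[i, topo$dest_mi[i]] + pmi[i]
    if (pst[i] > 0)
      M[i, topo$dest_stroke[i]] <- M[i, topo$dest_stroke[i]] + pst[i]
    resid <- 1 - pd[i] - pmi[i] - pst[i]  # tunnel exits; chronic stays
    M[i, topo$dest_chronic[i]] <- M[i, topo$dest_chronic[i]] + resid
  }
  M[cbind(which(space$absorbing), which(space$absorbing))] <- 1
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    bad <- space$name[which.max(abs(rs - 1))]
    stop("row for state '", bad, "' fails to normalize (sum = ",
         format(rs[which.max(abs(rs - 1))], digits = 17), ")")
  }
  M
}

#' Serialize a state space to JSON
#'
#' @param space A `state_space`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
state_space_json <- function(space, path = NULL) {
  lst <- lapply(seq_len(nrow(space)), function(i) {
    list(name = space$name[i], category = space$category[i],
         phase = space$phase[i], tunnel = space$tunnel[i],
         absorbing = space$absorbing[i],
         components = space$components[[i]])
  })
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
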