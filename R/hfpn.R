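#' @keywords internal
#' @importFrom stats simulate coef predict residuals
#' @importFrom graphics plot
#' @importFrom utils head str
"_PACKAGE"

# Evaluate a polynomial with ascending coefficients c0..cd at (vector) t.
poly_eval <- function(coefficients, t) {
  out <- rep(0, length(t))
  for (i in rev(seq_along(coefficients))) out <- out * t + coefficients[i]
  out
}

#' Polynomial rate law of simulation time
#'
#' A continuous transition's firing speed as an explicit polynomial of the
#' simulation clock `t` (minutes), valid on a sub-interval of the model's
#' 0--15 min approximation window. Outside `valid_interval` the rate is zero
#' (the interval is treated as half-open, `[lo, hi)`, at evaluation time).
#'
#' @param coefficients numeric vector `c0..cd` (ascending powers of `t`),
#'   degree at most 4; units: relative fluorescence (x1000) per minute.
#' @param valid_interval length-2 numeric, contained in `[0, 15]` minutes.
#' @return object of class `rate_law`.
#' @export
rate_law <- function(coefficients, valid_interval = c(0, 15)) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            length(coefficients) <= 5L, all(is.finite(coefficients)),
            length(valid_interval) == 2L, valid_interval[1] < valid_interval[2])
  structure(list(coefficients = as.numeric(coefficients),
                 valid_interval = as.numeric(valid_interval)),
            class = "rate_law")
}

#' Place of a hybrid functional Petri net
#'
#' Places hold the net's state: token counts (discrete), real amounts
#' (continuous), or an opaque payload flag (generic, structural only).
#'
#' @param id short unique identifier.
#' @param kind `"discrete"`, `"continuous"` or `"generic"`.
#' @param initial_marking nonnegative number (integer for discrete places).
#'   Places with `allow_negative = TRUE` may carry and reach negative values
#'   (used for signed observables such as NADH fluorescence change and the
#'   electric potential).
#' @param label free-text description.
#' @param allow_negative logical; exempts the place from clamping at zero.
#' @return object of class `hfpn_place`.
#' @export
place <- function(id, kind = c("continuous", "discrete", "generic"),
                  initial_marking = 0, label = id, allow_negative = FALSE) {
  kind <- match.arg(kind)
  structure(list(id = as.character(id), kind = kind,
                 initial_marking = as.numeric(initial_marking),
                 label = as.character(label),
                 allow_negative = isTRUE(allow_negative)),
            class = "hfpn_place")
}

#' Transition of a hybrid functional Petri net
#'
#' Continuous transitions fire at a real-valued speed given by a [rate_law()];
#' discrete transitions fire atomically once their `delay` (minutes) has
#' elapsed and their input arcs enable them; generic transitions are
#' structural placeholders.
#'
#' @param id short unique identifier.
#' @param kind `"continuous"`, `"discrete"` or `"generic"`.
#' @param rate a [rate_law()] (continuous transitions only).
#' @param delay nonnegative delay in minutes (discrete transitions only).
#' @param label free-text description.
#' @return object of class `hfpn_transition`.
#' @export
transition <- function(id, kind = c("continuous", "discrete", "generic"),
                       rate = NULL, delay = NULL, label = id) {
  kind <- match.arg(kind)
  structure(list(id = as.character(id), kind = kind, rate = rate,
                 delay = if (is.null(delay)) NULL else as.numeric(delay),
                 label = as.character(label)),
            class = "hfpn_transition")
}

#' Arc of a hybrid functional Petri net
#'
#' Normal arcs move marking (weighted); test arcs enable a transition when the
#' source place's marking is at least the threshold, without consuming it;
#' inhibitory arcs disable the transition when the marking reaches the
#' threshold (strictly below the threshold enables). Test and inhibitory arcs
#' point from a place to a transition only and never change any marking.
#'
#' @param source,target place/transition ids; every arc connects a place and a
#'   transition (the graph is bipartite).
#' @param kind `"normal"`, `"test"` or `"inhibitory"`.
#' @param weight nonnegative weight (normal) or threshold (test/inhibitory).
#' @return object of class `hfpn_arc`.
#' @export
arc <- function(source, target, kind = c("normal", "test", "inhibitory"),
                weight = 1) {
  kind <- match.arg(kind)
  structure(list(source = as.character(source), target = as.character(target),
                 kind = kind, weight_or_threshold = as.numeric(weight)),
            class = "hfpn_arc")
}

#' Assemble a hybrid functional Petri net
#'
#' Collects places, transitions and arcs into a net. Assembly does not
#' validate; run [validate_hfpn()] to obtain diagnostics.
#'
#' @param places list of [place()] objects.
#' @param transitions list of [transition()] objects.
#' @param arcs list of [arc()] objects.
#' @param metadata optional named list carried along (e.g. condition,
#'   observable map) and preserved by the YAML round-trip.
#' @return object of class `hfpn`.
#' @export
hfpn <- function(places, transitions, arcs, metadata = list()) {
  structure(list(places = places, transitions = transitions, arcs = arcs,
                 metadata = metadata),
            class = "hfpn")
}

#' @export
print.hfpn <- function(x, ...) {
  cat("Hybrid functional Petri net\n")
  cat(sprintf("  places:      %d (%s)\n", length(x$places),
              paste(table(vapply(x$places, `[[`, "", "kind")), collapse = "/")))
  cat(sprintf("  transitions: %d\n", length(x$transitions)))
  cat(sprintf("  arcs:        %d\n", length(x$arcs)))
  if (!is.null(x$metadata$condition))
    cat(sprintf("  condition:   %s\n", x$metadata$condition))
  invisible(x)
}

#' Validate a net against the HFPN structural invariants
#'
#' Checks id uniqueness, bipartiteness, arc endpoints, arc-kind direction
#' rules, marking-sign and integer constraints, rate/delay exclusivity, rate
#' degree and validity window. Returns diagnostics rather than raising.
#'
#' @param net an [hfpn()] object.
#' @return character vector, one message per violation (empty if the net is
#'   well formed); each message names the offending element id.
#' @export
validate_hfpn <- function(net) {
  d <- character(0)
  say <- function(...) d[[length(d) + 1L]] <<- sprintf(...)

  pid <- vapply(net$places, `[[`, "", "id")
  tid <- vapply(net$transitions, `[[`, "", "id")
  for (i in unique(pid[duplicated(pid)])) say("duplicate place id '%s'", i)
  for (i in unique(tid[duplicated(tid)])) say("duplicate transition id '%s'", i)
  for (i in intersect(pid, tid))
    say("id '%s' used for both a place and a transition", i)
  if (length(net$transitions) == 0L) say("net has no transitions")

  for (p in net$places) {
    if (!p$kind %in% c("discrete", "continuous", "generic"))
      say("place '%s': unknown kind '%s'", p$id, p$kind)
    if (!is.finite(p$initial_marking))
      say("place '%s': initial marking is not finite", p$id)
    else {
      if (p$kind == "discrete" &&
          (p$initial_marking < 0 || p$initial_marking != round(p$initial_marking)))
        say("place '%s': discrete initial marking must be a nonnegative integer",
            p$id)
      if (p$kind == "continuous" && !p$allow_negative && p$initial_marking < 0)
        say("place '%s': negative initial marking without allow_negative", p$id)
    }
  }

  for (tr in net$transitions) {
    if (!tr$kind %in% c("discrete", "continuous", "generic"))
      say("transition '%s': unknown kind '%s'", tr$id, tr$kind)
    if (tr$kind == "continuous") {
      if (is.null(tr$rate))
        say("transition '%s': continuous transition lacks a rate law", tr$id)
      else {
        if (length(tr$rate$coefficients) > 5L)
          say("transition '%s': rate polynomial degree exceeds 4", tr$id)
        vi <- tr$rate$valid_interval
        if (vi[1] < 0 || vi[2] > 15)
          say("transition '%s': rate valid_interval outside [0, 15] min", tr$id)
      }
      if (!is.null(tr$delay))
        say("transition '%s': continuous transition must not carry a delay",
            tr$id)
    }
    if (tr$kind == "discrete") {
      if (is.null(tr$delay) || tr$delay < 0)
        say("transition '%s': discrete transition needs a nonnegative delay",
            tr$id)
      if (!is.null(tr$rate))
        say("transition '%s': discrete transition must not carry a rate", tr$id)
    }
  }

  for (a in net$arcs) {
    aid <- sprintf("%s->%s", a$source, a$target)
    s_p <- a$source %in% pid; s_t <- a$source %in% tid
    t_p <- a$target %in% pid; t_t <- a$target %in% tid
    if (!(s_p || s_t)) say("arc '%s': unknown source '%s'", aid, a$source)
    if (!(t_p || t_t)) say("arc '%s': unknown target '%s'", aid, a$target)
    if ((s_p && t_p) || (s_t && t_t))
      say("arc '%s': must connect a place and a transition (bipartite)", aid)
    if (a$kind %in% c("test", "inhibitory") && !(s_p && t_t))
      say("arc '%s': %s arcs must point place -> transition", aid, a$kind)
    if (!a$kind %in% c("normal", "test", "inhibitory"))
      say("arc '%s': unknown kind '%s'", aid, a$kind)
    if (!is.finite(a$weight_or_threshold) || a$weight_or_threshold < 0)
      say("arc '%s': weight/threshold must be a nonnegative number", aid)
  }
  d
}

stop_if_invalid <- function(net) {
  d <- validate_hfpn(net)
  if (length(d))
    stop("invalid net:\n  ", paste(d, collapse = "\n  "), call. = FALSE)
  invisible(net)
}

# --- execution -------------------------------------------------------------

#' Initial simulation state of a net
#'
#' @param net a validated [hfpn()] object.
#' @return list with `time` (minutes), `marking` (named numeric vector),
#'   `event_log` (data.frame of discrete firings), `clamp_log` (data.frame of
#'   clamp events) and internal bookkeeping.
#' @export
init_state <- function(net) {
  marking <- vapply(net$places, `[[`, 0, "initial_marking")
  names(marking) <- vapply(net$places, `[[`, "", "id")
  tid <- vapply(net$transitions, `[[`, "", "id")
  fired <- stats::setNames(rep(FALSE, length(tid)), tid)
  list(time = 0,
       marking = marking,
       event_log = data.frame(time = numeric(0), transition = character(0)),
       clamp_log = data.frame(time = numeric(0), place = character(0)),
       fired = fired)
}

# Compile arc lists into per-transition index vectors for fast stepping.
compile_net <- function(net) {
  pid <- vapply(net$places, `[[`, "", "id")
  allow_neg <- vapply(net$places, `[[`, FALSE, "allow_negative")
  names(allow_neg) <- pid
  comp <- list(pid = pid, allow_neg = allow_neg, transitions = list())
  for (tr in net$transitions) {
    in_norm_p <- integer(0); in_norm_w <- numeric(0)
    out_p <- integer(0); out_w <- numeric(0)
    en_p <- integer(0); en_thr <- numeric(0); en_inhib <- logical(0)
    for (a in net$arcs) {
      if (a$target == tr$id && a$source %in% pid) {
        j <- match(a$source, pid)
        if (a$kind == "normal") {
          in_norm_p <- c(in_norm_p, j); in_norm_w <- c(in_norm_w, a$weight_or_threshold)
          en_p <- c(en_p, j); en_thr <- c(en_thr, a$weight_or_threshold)
          en_inhib <- c(en_inhib, FALSE)
        } else {
          en_p <- c(en_p, j); en_thr <- c(en_thr, a$weight_or_threshold)
          en_inhib <- c(en_inhib, a$kind == "inhibitory")
        }
      }
      if (a$source == tr$id && a$target %in% pid && a$kind == "normal") {
        out_p <- c(out_p, match(a$target, pid))
        out_w <- c(out_w, a$weight_or_threshold)
      }
    }
    comp$transitions[[tr$id]] <-
      list(id = tr$id, kind = tr$kind, rate = tr$rate, delay = tr$delay,
           in_p = in_norm_p, in_w = in_norm_w, out_p = out_p, out_w = out_w,
           en_p = en_p, en_thr = en_thr, en_inhib = en_inhib)
  }
  comp
}

enabled_compiled <- function(ct, marking) {
  if (length(ct$en_p)) {
    m <- marking[ct$en_p]
    ok <- ifelse(ct$en_inhib, m < ct$en_thr, m >= ct$en_thr)
    all(ok)
  } else TRUE
}

#' Is a transition enabled in the current state?
#'
#' A transition is enabled when every input normal/test arc's source marking
#' is at least the arc weight/threshold and every inhibitory arc's source
#' marking is strictly below its threshold.
#'
#' @param net an [hfpn()] object.
#' @param state a state from [init_state()] / [hfpn_step()].
#' @param transition_id transition id.
#' @return logical scalar.
#' @export
is_enabled <- function(net, state, transition_id) {
  comp <- compile_net(net)
  ct <- comp$transitions[[transition_id]]
  if (is.null(ct)) stop("unknown transition id '", transition_id, "'")
  enabled_compiled(ct, state$marking)
}

rate_at <- function(rl, t, id) {
  vi <- rl$valid_interval
  if (t < vi[1] || t >= vi[2]) return(0)
  r <- poly_eval(rl$coefficients, t)
  if (!is.finite(r))
    stop(sprintf("nonfinite rate for transition '%s' at t = %g min", id, t))
  r
}

step_compiled <- function(comp, state, dt) {
  t0 <- state$time
  marking <- state$marking
  # discrete firings (delay elapsed, enabled, at most once per run), in
  # lexicographic id order, atomically before the continuous update
  disc <- Filter(function(ct) ct$kind == "discrete", comp$transitions)
  if (length(disc)) {
    for (ct in disc[order(names(disc))]) {
      if (!state$fired[[ct$id]] && t0 >= ct$delay &&
          enabled_compiled(ct, marking)) {
        if (length(ct$in_p)) marking[ct$in_p] <- marking[ct$in_p] - ct$in_w
        if (length(ct$out_p)) marking[ct$out_p] <- marking[ct$out_p] + ct$out_w
        state$fired[[ct$id]] <- TRUE
        state$event_log <- rbind(state$event_log,
                                 data.frame(time = t0, transition = ct$id))
      }
    }
  }
  # continuous update: enabling checked on the pre-step marking, all flows
  # applied simultaneously; rates evaluated at the interval midpoint
  tm <- t0 + dt / 2
  delta <- numeric(length(marking))
  for (ct in comp$transitions) {
    if (ct$kind != "continuous") next
    if (!enabled_compiled(ct, marking)) next
    r <- rate_at(ct$rate, tm, ct$id)
    if (r == 0) next
    flow <- r * dt
    if (length(ct$out_p)) delta[ct$out_p] <- delta[ct$out_p] + ct$out_w * flow
    if (length(ct$in_p)) delta[ct$in_p] <- delta[ct$in_p] - ct$in_w * flow
  }
  marking <- marking + delta
  neg <- which(marking < 0 & !comp$allow_neg)
  if (length(neg)) {
    marking[neg] <- 0
    state$clamp_log <- rbind(state$clamp_log,
                             data.frame(time = t0 + dt, place = comp$pid[neg]))
  }
  state$marking <- marking
  state$time <- t0 + dt
  state
}

# Same semantics as step_compiled, but appends log entries to lists (O(1)
# amortized) for use inside the simulation loop; logs are bound to data.frames
# once at the end of the run.
step_compiled_listlog <- function(comp, state, dt) {
  t0 <- state$time
  marking <- state$marking
  disc <- Filter(function(ct) ct$kind == "discrete", comp$transitions)
  if (length(disc)) {
    for (ct in disc[order(names(disc))]) {
      if (!state$fired[[ct$id]] && t0 >= ct$delay &&
          enabled_compiled(ct, marking)) {
        if (length(ct$in_p)) marking[ct$in_p] <- marking[ct$in_p] - ct$in_w
        if (length(ct$out_p)) marking[ct$out_p] <- marking[ct$out_p] + ct$out_w
        state$fired[[ct$id]] <- TRUE
        state$event_log[[length(state$event_log) + 1L]] <-
          data.frame(time = t0, transition = ct$id)
      }
    }
  }
  tm <- t0 + dt / 2
  delta <- numeric(length(marking))
  for (ct in comp$transitions) {
    if (ct$kind != "continuous") next
    if (!enabled_compiled(ct, marking)) next
    r <- rate_at(ct$rate, tm, ct$id)
    if (r == 0) next
    flow <- r * dt
    if (length(ct$out_p)) delta[ct$out_p] <- delta[ct$out_p] + ct$out_w * flow
    if (length(ct$in_p)) delta[ct$in_p] <- delta[ct$in_p] - ct$in_w * flow
  }
  marking <- marking + delta
  neg <- which(marking < 0 & !comp$allow_neg)
  if (length(neg)) {
    marking[neg] <- 0
    state$clamp_log[[length(state$clamp_log) + 1L]] <-
      data.frame(time = t0 + dt, place = comp$pid[neg])
  }
  state$marking <- marking
  state$time <- t0 + dt
  state
}

# A net qualifies for the vectorized path when no transition's enabling can
# change during the run: every enabling arc reads a place that no transition
# writes, so each transition is statically enabled or statically dead, and no
# discrete transition can ever fire. Rates depend only on time, so the whole
# marking evolution is then a cumulative sum with per-step reflection at zero
# (Skorokhod construction) for clamped places -- identical, step for step, to
# the general loop.
classify_static <- function(comp, marking) {
  written <- sort(unique(unlist(lapply(comp$transitions,
                                       function(ct) c(ct$in_p, ct$out_p)))))
  active <- character(0)
  for (ct in comp$transitions) {
    if (any(ct$en_p %in% written)) {
      # dynamic enabling: fast path only if the static part already kills it
      st <- !(ct$en_p %in% written)
      m <- marking[ct$en_p[st]]
      dead <- length(m) &&
        !all(ifelse(ct$en_inhib[st], m < ct$en_thr[st], m >= ct$en_thr[st]))
      if (!dead) return(NULL)
    } else if (enabled_compiled(ct, marking)) {
      if (ct$kind == "discrete") return(NULL)  # would fire: use the loop
      if (ct$kind == "continuous") active <- c(active, ct$id)
    }
  }
  active
}

simulate_fast <- function(comp, state, dt, n_steps, active_ids) {
  npl <- length(state$marking)
  tm <- (seq_len(n_steps) - 1L) * dt + dt / 2
  delta <- matrix(0, nrow = n_steps, ncol = npl)
  for (tid in active_ids) {
    ct <- comp$transitions[[tid]]
    rl <- ct$rate
    inside <- tm >= rl$valid_interval[1] & tm < rl$valid_interval[2]
    if (!any(inside)) next
    r <- numeric(n_steps)
    r[inside] <- poly_eval(rl$coefficients, tm[inside])
    if (any(!is.finite(r)))
      stop(sprintf("nonfinite rate for transition '%s' at t = %g min",
                   tid, tm[which(!is.finite(r))[1]]))
    flow <- r * dt
    for (j in seq_along(ct$out_p))
      delta[, ct$out_p[j]] <- delta[, ct$out_p[j]] + ct$out_w[j] * flow
    for (j in seq_along(ct$in_p))
      delta[, ct$in_p[j]] <- delta[, ct$in_p[j]] - ct$in_w[j] * flow
  }
  mark_mat <- matrix(NA_real_, nrow = n_steps, ncol = npl)
  clamp_t <- numeric(0); clamp_p <- character(0)
  for (p in seq_len(npl)) {
    s <- state$marking[p] + cumsum(delta[, p])
    if (comp$allow_neg[p] || all(s >= 0)) {
      mark_mat[, p] <- s
    } else {
      m <- s - pmin(0, cummin(s))
      prev <- c(state$marking[p], m[-n_steps])
      ev <- which(prev + delta[, p] < 0)
      mark_mat[, p] <- m
      clamp_t <- c(clamp_t, ev * dt)
      clamp_p <- c(clamp_p, rep(comp$pid[p], length(ev)))
    }
  }
  ord <- order(clamp_t)
  list(mark_mat = mark_mat,
       clamp_log = data.frame(time = clamp_t[ord], place = clamp_p[ord]),
       event_log = state$event_log)
}

#' Advance a simulation state by one time step
#'
#' Discrete transitions whose delay has elapsed fire atomically first (in
#' lexicographic id order, at most once per run); then every enabled
#' continuous transition moves marking along its normal arcs by
#' `rate(t + dt/2) * dt * weight` (midpoint quadrature; rates are explicit
#' functions of time). Markings of places without `allow_negative` are clamped
#' at zero and each clamp is logged in `clamp_log`.
#'
#' @param net an [hfpn()] object.
#' @param state simulation state.
#' @param dt positive step, minutes.
#' @return the advanced state.
#' @export
hfpn_step <- function(net, state, dt) {
  stopifnot(dt > 0)
  step_compiled(compile_net(net), state, dt)
}

#' Simulate a hybrid functional Petri net
#'
#' Fixed-step midpoint integration of all continuous transitions, with
#' discrete firings interleaved. Because every rate law is an explicit
#' polynomial of time, the midpoint rule integrates degree <= 1 rates exactly
#' and has global error O(dt^2) otherwise, far below the fitting noise of the
#' fluorescence data the model represents.
#'
#' @param net a validated [hfpn()] object.
#' @param t_end end time, minutes; must lie in the model's approximation
#'   window `[0, 15]` unless `allow_beyond_validity = TRUE` (then a warning is
#'   issued).
#' @param dt integration step (minutes), default 0.001.
#' @param sample_every sampling interval (minutes); must be a multiple of
#'   `dt` and satisfy `dt <= sample_every <= t_end`.
#' @param allow_beyond_validity override the 15-min cap (logged warning).
#' @param engine `"auto"` (default) uses a vectorized evaluation whenever the
#'   net's enabling structure cannot change during the run (it is exact,
#'   step-for-step identical to the general loop); `"stepwise"` forces the
#'   general per-step loop (useful for cross-validation and for nets with
#'   dynamic enabling or discrete firings, where it is selected automatically).
#' @return an `hfpn_trajectory`: a data.frame with column `time` and one
#'   column per place, with attributes `event_log` and `clamp_log`.
#' @export
simulate_hfpn <- function(net, t_end, dt = 0.001, sample_every = dt,
                          allow_beyond_validity = FALSE,
                          engine = c("auto", "stepwise")) {
  engine <- match.arg(engine)
  stopifnot(is.numeric(t_end), t_end >= 0, dt > 0)
  if (t_end > 15 && !allow_beyond_validity)
    stop("t_end exceeds the 15-min approximation window; ",
         "set allow_beyond_validity = TRUE to override")
  if (t_end > 15) warning("simulating beyond the 0-15 min validity window")
  comp <- compile_net(stop_if_invalid(net))
  state <- init_state(net)

  if (t_end == 0) {
    out <- data.frame(time = 0, t(state$marking), check.names = FALSE)
  } else {
    if (sample_every < dt || sample_every > t_end)
      stop("need dt <= sample_every <= t_end")
    k <- sample_every / dt
    if (abs(k - round(k)) > 1e-8)
      stop("sample_every must be an integer multiple of dt")
    k <- as.integer(round(k))
    n_samp <- as.integer(floor(t_end / sample_every + 1e-9))
    n_steps <- n_samp * k
    grid <- (0:n_samp) * sample_every
    active <- if (engine == "auto") classify_static(comp, state$marking) else NULL
    if (!is.null(active)) {
      res <- simulate_fast(comp, state, dt, n_steps, active)
      mat <- rbind(state$marking, res$mark_mat[seq_len(n_samp) * k, , drop = FALSE])
      state$clamp_log <- res$clamp_log
    } else {
      mat <- matrix(NA_real_, nrow = n_samp + 1L, ncol = length(state$marking))
      mat[1L, ] <- state$marking
      state$clamp_log <- list()
      state$event_log <- list()
      step_i <- 0L
      for (s in seq_len(n_samp)) {
        for (j in seq_len(k)) {
          state$time <- step_i * dt        # avoid accumulated float drift
          state <- step_compiled_listlog(comp, state, dt)
          step_i <- step_i + 1L
        }
        mat[s + 1L, ] <- state$marking
      }
      state$clamp_log <- if (length(state$clamp_log))
        do.call(rbind, state$clamp_log) else
        data.frame(time = numeric(0), place = character(0))
      state$event_log <- if (length(state$event_log))
        do.call(rbind, state$event_log) else
        data.frame(time = numeric(0), transition = character(0))
    }
    out <- data.frame(time = grid, mat, check.names = FALSE)
    names(out) <- c("time", comp$pid)
    rownames(out) <- NULL
  }
  structure(out,
            class = c("hfpn_trajectory", "data.frame"),
            event_log = state$event_log,
            clamp_log = state$clamp_log,
            dt = dt,
            metadata = net$metadata)
}

#' @rdname simulate_hfpn
#' @param object an `hfpn` net (for the [stats::simulate()] generic).
#' @param nsim unused (the engine is deterministic); must be 1.
#' @param seed unused; the engine contains no randomness.
#' @param ... passed to [simulate_hfpn()].
#' @export
simulate.hfpn <- function(object, nsim = 1, seed = NULL, ...) {
  if (nsim != 1) stop("the HFPN engine is deterministic; nsim must be 1")
  simulate_hfpn(object, ...)
}

#' @export
print.hfpn_trajectory <- function(x, ...) {
  cat(sprintf("HFPN trajectory: %d samples x %d places, t in [%g, %g] min\n",
              nrow(x), ncol(x) - 1L, min(x$time), max(x$time)))
  ev <- attr(x, "event_log")
  if (!is.null(ev) && nrow(ev))
    cat(sprintf("  discrete firings: %d\n", nrow(ev)))
  cl <- attr(x, "clamp_log")
  if (!is.null(cl) && nrow(cl))
    cat(sprintf("  clamp events: %d\n", nrow(cl)))
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Plot place trajectories
#'
#' @param x an `hfpn_trajectory`.
#' @param places character vector of place columns (default: all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.hfpn_trajectory <- function(x, places = setdiff(names(x), "time"), ...) {
  graphics::matplot(x$time, as.matrix(as.data.frame(x)[places]), type = "l",
                    xlab = "time (min)", ylab = "marking", ...)
  graphics::legend("topleft", legend = places, lty = seq_along(places),
                   col = seq_along(places), bty = "n", cex = 0.8)
  invisible(x)
}

# --- YAML serialization ----------------------------------------------------

#' Read / write a net as YAML
#'
#' The document has top-level keys `places`, `transitions`, `arcs` (field
#' names as in the constructors; a continuous transition's rate is a mapping
#' with `coefficients` and `valid_interval`) plus an optional `metadata`
#' block. A write followed by a read reproduces the net.
#'
#' @param path file path.
#' @return [read_hfpn_yaml()] returns an `hfpn`; [write_hfpn_yaml()] returns
#'   `path` invisibly.
#' @export
read_hfpn_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!all(c("places", "transitions", "arcs") %in% names(doc)))
    stop("YAML net must have top-level keys places, transitions, arcs")
  pl <- lapply(doc$places, function(p)
    place(p$id, p$kind, p$initial_marking, p$label %||% p$id,
          isTRUE(p$allow_negative)))
  tr <- lapply(doc$transitions, function(tt) {
    rl <- if (!is.null(tt$rate))
      rate_law(unlist(tt$rate$coefficients), unlist(tt$rate$valid_interval))
    transition(tt$id, tt$kind, rate = rl, delay = tt$delay,
               label = tt$label %||% tt$id)
  })
  ar <- lapply(doc$arcs, function(a)
    arc(a$source, a$target, a$kind, a$weight_or_threshold))
  hfpn(pl, tr, ar, metadata = doc$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_hfpn_yaml
#' @param net an [hfpn()] object.
#' @export
write_hfpn_yaml <- function(net, path) {
  doc <- list(
    places = lapply(net$places, function(p) {
      out <- list(id = p$id, kind = p$kind,
                  initial_marking = p$initial_marking, label = p$label)
      if (p$allow_negative) out$allow_negative <- TRUE
      out
    }),
    transitions = lapply(net$transitions, function(tt) {
      out <- list(id = tt$id, kind = tt$kind, label = tt$label)
      if (!is.null(tt$rate))
        out$rate <- list(coefficients = as.list(tt$rate$coefficients),
                         valid_interval = as.list(tt$rate$valid_interval))
      if (!is.null(tt$delay)) out$delay <- tt$delay
      out
    }),
    arcs = lapply(net$arcs, function(a)
      list(source = a$source, target = a$target, kind = a$kind,
           weight_or_threshold = a$weight_or_threshold))
  )
  if (length(net$metadata)) doc$metadata <- net$metadata
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}
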