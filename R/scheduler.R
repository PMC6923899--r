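# In-process re-implementation of a fault-tolerant FIFO task-queue protocol:
# a server-side queue hands tasks to workers, collects results idempotently,
# and reloads the in-flight tasks of failed workers.

#' Sentinel returned when the task queue is empty
#' @export
NO_TASK <- structure("NO_TASK", class = "no_task")

#' Create a task queue
#'
#' The queue partitions the initial task set into `pending` (FIFO),
#' `in_flight` (per worker) and `completed`; the three sets stay pairwise
#' disjoint and their union constant across every operation.
#'
#' @param tasks Character vector of unique task IDs.
#' @return A `task_queue` object (environment).
#' @export
task_queue <- function(tasks) {
  tasks <- as.character(tasks)
  stopifnot(!anyDuplicated(tasks))
  q <- new.env(parent = emptyenv())
  q$pending <- tasks
  q$in_flight <- character(0)      # named: task -> worker
  q$completed <- character(0)
  q$results <- list()
  q$workers <- character(0)
  class(q) <- "task_queue"
  q
}

#' @export
print.task_queue <- function(x, ...) {
  cat(sprintf("task queue: %d pending, %d in flight, %d completed\n",
              length(x$pending), length(x$in_flight), length(x$completed)))
  invisible(x)
}

#' Check the conservation invariant of a queue
#' @param q A [task_queue()].
#' @param tasks The initial task set.
#' @return `TRUE` if pending, in-flight and completed are pairwise disjoint
#'   and their union equals `tasks`.
#' @export
queue_invariant_holds <- function(q, tasks) {
  sets <- list(q$pending, names(q$in_flight), q$completed)
  total <- unlist(sets)
  !anyDuplicated(total) && setequal(total, tasks)
}

#' Request the next task (FIFO)
#'
#' Moves the head of the pending queue into the worker's in-flight set;
#' returns [NO_TASK] when the queue is empty.
#'
#' @param q A [task_queue()].
#' @param worker_id Worker identifier (registered on first contact).
#' @return A task ID, or [NO_TASK].
#' @export
request_task <- function(q, worker_id) {
  q$workers <- union(q$workers, worker_id)
  if (!length(q$pending)) return(NO_TASK)
  task <- q$pending[1]
  q$pending <- q$pending[-1]
  q$in_flight[task] <- worker_id
  task
}

#' Record a completed task (idempotent collect)
#'
#' Moves the task from in-flight to completed and stores the result. A
#' completion for an already-completed task (the failure-reload race) is
#' ignored; completing a task assigned to a different worker is a protocol
#' error.
#'
#' @param q A [task_queue()].
#' @param worker_id Worker claiming completion.
#' @param task_id Task ID.
#' @param result Result reference to record.
#' @export
complete_task <- function(q, worker_id, task_id, result = TRUE) {
  if (task_id %in% q$completed) return(invisible(FALSE))  # duplicate
  owner <- q$in_flight[task_id]
  if (is.na(owner) || owner != worker_id)
    stop("protocol error: task '", task_id, "' is not in flight under worker '",
         worker_id, "'")
  q$in_flight <- q$in_flight[names(q$in_flight) != task_id]
  q$completed <- c(q$completed, task_id)
  q$results[[task_id]] <- result
  invisible(TRUE)
}

#' Handle a worker failure
#'
#' Returns every in-flight task of the failed worker to the tail of the
#' pending queue and deregisters the worker.
#'
#' @param q A [task_queue()].
#' @param worker_id The failed worker.
#' @return Character vector of reloaded task IDs.
#' @export
handle_worker_failure <- function(q, worker_id) {
  mine <- names(q$in_flight)[q$in_flight == worker_id]
  q$in_flight <- q$in_flight[!(names(q$in_flight) %in% mine)]
  q$pending <- c(q$pending, mine)
  q$workers <- setdiff(q$workers, worker_id)
  mine
}

#' Drive a worker pool over a task list
#'
#' Simulated in-process pool: workers repeatedly request, execute and
#' complete tasks until pending and in-flight are empty. Failures are
#' injected per executed task with probability `failure_rate` (the worker
#' crashes before completing; its tasks are reloaded and a fresh worker
#' replaces it). A task whose `worker_fn` raises `max_retries` consecutive
#' times is marked `"failed"` and the run continues. Workers listed in
#' `join_after` join mid-run after that many completed dispatches.
#'
#' @param tasks Character vector of task IDs.
#' @param worker_fn Function of one task ID returning its result.
#' @param n_workers Number of initial workers.
#' @param failure_rate Injected crash probability per dispatch, in `[0, 1)`.
#' @param seed Integer seed driving the injected-failure schedule.
#' @param max_retries Consecutive error budget per task (default 3).
#' @param join_after Optional integer vector: dispatch counts at which an
#'   extra worker joins.
#' @return Named list: task ID -> `list(status = "ok"|"failed", value =)`.
#' @export
run_pool <- function(tasks, worker_fn, n_workers = 4, failure_rate = 0,
                     seed = 1, max_retries = 3, join_after = NULL) {
  stopifnot(failure_rate >= 0, failure_rate < 1)
  set.seed(seed)
  q <- task_queue(tasks)
  failed <- character(0)
  errors <- stats::setNames(integer(length(tasks)), tasks)
  workers <- paste0("w", seq_len(n_workers))
  next_worker_id <- n_workers
  dispatches <- 0L

  while (length(q$pending) || length(q$in_flight)) {
    for (w in workers) {
      if (!length(q$pending) && !length(q$in_flight)) break
      task <- request_task(q, w)
      if (inherits(task, "no_task")) next
      dispatches <- dispatches + 1L
      if (failure_rate > 0 && stats::runif(1) < failure_rate) {
        handle_worker_failure(q, w)
        next_worker_id <- next_worker_id + 1L
        workers[workers == w] <- paste0("w", next_worker_id)
        next
      }
      res <- tryCatch(list(ok = TRUE, value = worker_fn(task)),
                      error = function(e) list(ok = FALSE, value = conditionMessage(e)))
      if (res$ok) {
        complete_task(q, w, task, res$value)
      } else {
        errors[task] <- errors[task] + 1L
        if (errors[task] >= max_retries) {
          failed <- c(failed, task)
          complete_task(q, w, task, NULL)  # retire the task
        } else {
          # return the task for a retry
          q$in_flight <- q$in_flight[names(q$in_flight) != task]
          q$pending <- c(q$pending, task)
        }
      }
      if (!is.null(join_after) && dispatches %in% join_after) {
        next_worker_id <- next_worker_id + 1L
        workers <- c(workers, paste0("w", next_worker_id))
      }
      stopifnot(queue_invariant_holds(q, tasks))
    }
  }
  out <- lapply(stats::setNames(as.character(tasks), tasks), function(t) {
    if (t %in% failed) list(status = "failed", value = NULL)
    else list(status = "ok", value = q$results[[t]])
  })
  out
}
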