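#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>

// Stack-machine evaluation of compiled Boolean rules.
//
// A rule is compiled (R side) to a postfix integer program:
//   1 idx        push current[idx]
//   2            NOT
//   3 n          AND of top n values
//   4 n          OR of top n values
//   5 idx w      ALL-window: node idx active in every one of the w most
//                recent completed iterations (missing history counts 0)
//   6 idx w      ANY-window: active in at least one of them
// Node indices are 0-based. Window terms read only completed-iteration
// history (column t-1 backwards), never the partially updated sweep.

static inline int eval_prog(const int* code, int len,
                            const uint8_t* cur,
                            const std::vector<uint8_t>& hist,
                            int n, int t,
                            std::vector<uint8_t>& stack) {
  int sp = 0;
  for (int p = 0; p < len;) {
    int op = code[p++];
    switch (op) {
    case 1:
      stack[sp++] = cur[code[p++]];
      break;
    case 2:
      stack[sp - 1] = !stack[sp - 1];
      break;
    case 3: {
      int k = code[p++];
      uint8_t v = 1;
      for (int i = 0; i < k; ++i) v = v && stack[sp - 1 - i];
      sp -= k;
      stack[sp++] = v;
      break;
    }
    case 4: {
      int k = code[p++];
      uint8_t v = 0;
      for (int i = 0; i < k; ++i) v = v || stack[sp - 1 - i];
      sp -= k;
      stack[sp++] = v;
      break;
    }
    case 5: {
      int idx = code[p++], w = code[p++];
      uint8_t v = 1;
      for (int i = 1; i <= w; ++i) {
        int tt = t - i;
        if (tt < 0 || !hist[(size_t)tt * n + idx]) { v = 0; break; }
      }
      stack[sp++] = v;
      break;
    }
    case 6: {
      int idx = code[p++], w = code[p++];
      uint8_t v = 0;
      for (int i = 1; i <= w; ++i) {
        int tt = t - i;
        if (tt >= 0 && hist[(size_t)tt * n + idx]) { v = 1; break; }
      }
      stack[sp++] = v;
      break;
    }
    default:
      Rcpp::stop("corrupt bytecode");
    }
  }
  return stack[0];
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".simulate_cpp")]]
Rcpp::IntegerVector simulate_cpp(Rcpp::List prog,
                                 int iterations, int repetitions,
                                 int scheme,  // 0 sync, 1 async sweep, 2 async single
                                 double seed,
                                 Rcpp::IntegerVector clamp,  // -1 free, 0/1 clamped
                                 Rcpp::IntegerVector init) {
  const int n = prog.size();
  const int T = iterations, R = repetitions;
  std::vector<std::vector<int>> code(n);
  int maxlen = 1;
  for (int j = 0; j < n; ++j) {
    Rcpp::IntegerVector v = prog[j];
    code[j].assign(v.begin(), v.end());
    maxlen = std::max(maxlen, (int)v.size());
  }
  Rcpp::IntegerVector out(Rcpp::no_init((size_t)R * T * n));
  out.attr("dim") = Rcpp::IntegerVector::create(R, T, n);
  std::vector<uint8_t> stack(maxlen + 1);
  std::vector<uint8_t> hist((size_t)(T + 1) * n);
  std::vector<uint8_t> cur(n);
  std::vector<int> perm(n);
  const uint64_t useed = (uint64_t)(int64_t)seed;

  for (int rep = 0; rep < R; ++rep) {
    std::mt19937_64 gen(splitmix64(useed ^ splitmix64((uint64_t)rep)));
    // initial state (iteration 0 of the history), clamps enforced
    for (int j = 0; j < n; ++j)
      hist[j] = clamp[j] >= 0 ? (uint8_t)clamp[j] : (uint8_t)init[j];
    for (int t = 1; t <= T; ++t) {
      const uint8_t* prev = &hist[(size_t)(t - 1) * n];
      std::copy(prev, prev + n, cur.begin());
      if (scheme == 0) {          // synchronous: all nodes from t-1 state
        uint8_t* nxt = &hist[(size_t)t * n];
        for (int j = 0; j < n; ++j)
          nxt[j] = clamp[j] >= 0 ? (uint8_t)clamp[j]
                 : (uint8_t)eval_prog(code[j].data(), code[j].size(),
                                      prev, hist, n, t, stack);
      } else if (scheme == 1) {   // asynchronous sweep: fresh permutation
        for (int j = 0; j < n; ++j) perm[j] = j;
        for (int i = n - 1; i > 0; --i) {
          int k = (int)(gen() % (uint64_t)(i + 1));
          std::swap(perm[i], perm[k]);
        }
        for (int i = 0; i < n; ++i) {
          int j = perm[i];
          cur[j] = clamp[j] >= 0 ? (uint8_t)clamp[j]
                 : (uint8_t)eval_prog(code[j].data(), code[j].size(),
                                      cur.data(), hist, n, t, stack);
        }
        std::copy(cur.begin(), cur.end(), &hist[(size_t)t * n]);
      } else {                    // asynchronous single-node step
        int j = (int)(gen() % (uint64_t)n);
        cur[j] = clamp[j] >= 0 ? (uint8_t)clamp[j]
               : (uint8_t)eval_prog(code[j].data(), code[j].size(),
                                    cur.data(), hist, n, t, stack);
        std::copy(cur.begin(), cur.end(), &hist[(size_t)t * n]);
      }
      uint8_t* rec = &hist[(size_t)t * n];
      for (int j = 0; j < n; ++j)
        out[(size_t)rep + (size_t)R * (t - 1) + (size_t)R * T * j] = rec[j];
    }
  }
  return out;
}
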