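// Trie-indexed bounded-edit-distance dictionary lookup.
//
// Lookup propagates a Levenshtein dynamic-programming row down every trie
// edge and abandons a branch as soon as the row minimum exceeds the distance
// bound, which is what makes small bounds (<= 1 in routine use) fast on
// dictionaries of thousands of entries.

#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

struct TrieNode {
  std::map<char, int> kids;
  int word = -1; // index into the dictionary, -1 if not a terminal
};

typedef std::vector<TrieNode> Trie;

// [[Rcpp::export]]
SEXP cpp_trie_build(CharacterVector words) {
  Trie* trie = new Trie(1);
  for (int i = 0; i < words.size(); ++i) {
    std::string w = as<std::string>(words[i]);
    int node = 0;
    for (char c : w) {
      auto it = (*trie)[node].kids.find(c);
      if (it == (*trie)[node].kids.end()) {
        (*trie)[node].kids[c] = (int)trie->size();
        int nxt = (int)trie->size();
        trie->push_back(TrieNode());
        node = nxt;
      } else {
        node = it->second;
      }
    }
    (*trie)[node].word = i;
  }
  XPtr<Trie> ptr(trie, true);
  return ptr;
}

static void enumerate_rec(const Trie& trie, int node, std::string& prefix,
                          std::vector<std::string>& out) {
  if (trie[node].word >= 0) out.push_back(prefix);
  for (const auto& kv : trie[node].kids) {
    prefix.push_back(kv.first);
    enumerate_rec(trie, kv.second, prefix, out);
    prefix.pop_back();
  }
}

// [[Rcpp::export]]
CharacterVector cpp_trie_enumerate(SEXP ptr_) {
  XPtr<Trie> ptr(ptr_);
  std::vector<std::string> out;
  std::string prefix;
  enumerate_rec(*ptr, 0, prefix, out);
  return wrap(out);
}

static void lookup_rec(const Trie& trie, int node, const std::string& q,
                       int max_ed, const std::vector<int>& row,
                       std::vector<int>& hits, std::vector<int>& dists) {
  const int m = (int)q.size();
  if (trie[node].word >= 0 && row[m] <= max_ed) {
    hits.push_back(trie[node].word);
    dists.push_back(row[m]);
  }
  for (const auto& kv : trie[node].kids) {
    std::vector<int> nxt(m + 1);
    nxt[0] = row[0] + 1;
    int best = nxt[0];
    for (int j = 1; j <= m; ++j) {
      int sub = row[j - 1] + (q[j - 1] == kv.first ? 0 : 1);
      int ins = nxt[j - 1] + 1;
      int del = row[j] + 1;
      nxt[j] = std::min(sub, std::min(ins, del));
      if (nxt[j] < best) best = nxt[j];
    }
    if (best <= max_ed) {
      lookup_rec(trie, kv.second, q, max_ed, nxt, hits, dists);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_fuzzy_lookup(SEXP ptr_, CharacterVector queries, int max_ed) {
  XPtr<Trie> ptr(ptr_);
  std::vector<int> q_idx, w_idx, dist;
  for (int i = 0; i < queries.size(); ++i) {
    std::string q = as<std::string>(queries[i]);
    std::vector<int> row(q.size() + 1);
    for (size_t j = 0; j <= q.size(); ++j) row[j] = (int)j;
    std::vector<int> hits, dists;
    lookup_rec(*ptr, 0, q, max_ed, row, hits, dists);
    for (size_t k = 0; k < hits.size(); ++k) {
      q_idx.push_back(i + 1);
      w_idx.push_back(hits[k] + 1);
      dist.push_back(dists[k]);
    }
  }
  return DataFrame::create(_["query"] = q_idx, _["entry"] = w_idx,
                           _["distance"] = dist);
}

// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP ptr_) {
  return TYPEOF(ptr_) == EXTPTRSXP && R_ExternalPtrAddr(ptr_) != NULL;
}

// Longest-common-subsequence length per pair of (single-byte-symbol) strings.
// [[Rcpp::export]]
IntegerVector cpp_lcs_length(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]);
    std::string y = as<std::string>(b[i]);
    size_t nx = x.size(), ny = y.size();
    std::vector<int> prev(ny + 1, 0), cur(ny + 1, 0);
    for (size_t r = 1; r <= nx; ++r) {
      for (size_t c = 1; c <= ny; ++c) {
        if (x[r - 1] == y[c - 1]) {
          cur[c] = prev[c - 1] + 1;
        } else {
          cur[c] = std::max(prev[c], cur[c - 1]);
        }
      }
      std::swap(prev, cur);
    }
    out[i] = prev[ny];
  }
  return out;
}
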