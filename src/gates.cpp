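// Dense statevector gate kernel. Amplitude index i encodes basis |i> with
// bit j of i = qubit j (qubit 0 least significant). Gates arrive flattened:
// kind (0=X, 1=H, 2=Z, 3=RY), target bit mask, control bit mask, angle.

#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

// [[Rcpp::export(name = ".apply_circuit_cpp")]]
ComplexVector apply_circuit_cpp(ComplexVector amp_in, IntegerVector kind,
                                IntegerVector tmask, IntegerVector cmask,
                                NumericVector param) {
  ComplexVector amp_out(clone(amp_in));
  std::complex<double>* amp =
      reinterpret_cast<std::complex<double>*>(amp_out.begin());
  const int N = amp_out.size();
  const int G = kind.size();
  const double r = 1.0 / std::sqrt(2.0);

  for (int g = 0; g < G; ++g) {
    const int k = kind[g];
    const int tb = tmask[g];
    const int cm = cmask[g];
    if (k == 2) {  // Z: phase flip where controls and target are set
      for (int i = 0; i < N; ++i) {
        if ((i & cm) == cm && (i & tb)) amp[i] = -amp[i];
      }
      continue;
    }
    double c2 = 0.0, s2 = 0.0;
    if (k == 3) {
      c2 = std::cos(param[g] / 2.0);
      s2 = std::sin(param[g] / 2.0);
    }
    for (int i = 0; i < N; ++i) {
      if ((i & tb) || (i & cm) != cm) continue;
      const int j = i | tb;
      const std::complex<double> a0 = amp[i], a1 = amp[j];
      switch (k) {
        case 0:  // X
          amp[i] = a1;
          amp[j] = a0;
          break;
        case 1:  // H
          amp[i] = (a0 + a1) * r;
          amp[j] = (a0 - a1) * r;
          break;
        case 3:  // RY
          amp[i] = c2 * a0 - s2 * a1;
          amp[j] = s2 * a0 + c2 * a1;
          break;
      }
    }
  }
  return amp_out;
}
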