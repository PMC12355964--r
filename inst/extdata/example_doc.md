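Kinetic characterization of beta-galactosidase from Escherichia coli.

Enzyme: beta-galactosidase
Organism: Escherichia coli

Steady-state parameters were obtained by nonlinear regression.

| Substrate | Mutation | kcat (s^-1) | Km (μM) | pH | Temperature (°C) |
| --- | --- | --- | --- | --- | --- |
| lactose |  | 642 | 380 | 7.2 | 25 |
| lactose | E537Q | 0.18 | 95 | 7.2 | 25 |
| p-nitrophenyl phosphate |  | 120 min^-1 | 1.2 mM | 7.2 | 25 |

Initial rates were obtained from the linear phase of product formation.
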