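# effective configuration, 2026-09-23 22:07:46
package_version = 0.1.0
setting = 1
n = 50
seed = 7
important = Z1,Z2,Z7,Z8,X1
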