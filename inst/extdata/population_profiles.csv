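population,analyte,mean,se,n
POP1,IAA,123.7,2.31,3
POP1,GA,112.4,0.21,3
POP1,SA,136.9,0.43,3
POP1,kinetin,61.5,1.34,3
POP2,IAA,143.6,1.01,3
POP2,GA,164.7,0.42,3
POP2,SA,193.3,0.41,3
POP2,kinetin,42.6,1.4,3
POP3,IAA,119.8,1.0,3
POP3,GA,151.7,0.76,3
POP3,SA,172.5,0.52,3
POP3,kinetin,51.0,2.0,3
POP4,IAA,108.7,0.81,3
POP4,GA,143.1,0.56,3
POP4,SA,152.8,0.76,3
POP4,kinetin,53.8,0.98,3
POP5,IAA,128.6,0.89,3
POP5,GA,117.9,0.54,3
POP5,SA,135.6,0.56,3
POP5,kinetin,68.9,0.99,3
POP6,IAA,130.2,0.73,3
POP6,GA,127.8,0.94,3
POP6,SA,168.2,0.76,3
POP6,kinetin,57.2,0.67,3
POP7,IAA,116.5,0.98,3
POP7,GA,124.7,0.32,3
POP7,SA,150.9,0.89,3
POP7,kinetin,55.9,0.71,3
POP8,IAA,125.2,0.42,3
POP8,GA,141.9,2.1,3
POP8,SA,171.1,0.32,3
POP8,kinetin,59.9,0.45,3
POP9,IAA,124.3,0.37,3
POP9,GA,135.4,0.91,3
POP9,SA,146.9,0.43,3
POP9,kinetin,69.4,0.5,3
POP10,IAA,113.5,0.31,3
POP10,GA,149.5,0.87,3
POP10,SA,129.4,0.76,3
POP10,kinetin,66.9,1.2,3
POP11,IAA,138.3,0.54,3
POP11,GA,146.2,0.98,3
POP11,SA,164.1,0.67,3
POP11,kinetin,65.4,0.98,3
POP12,IAA,146.9,1.01,3
POP12,GA,148.5,0.78,3
POP12,SA,156.0,0.83,3
POP12,kinetin,58.3,0.23,3
POP13,IAA,308.791,0.87,3
POP13,GA,244.364,0.89,3
POP13,SA,382.657,0.88,3
POP13,kinetin,103.847,1.2,3
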