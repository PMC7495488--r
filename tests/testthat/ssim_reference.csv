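ssim
0.011346359907
0.052302615795
0.108575834827
0.099534938006
0.08790078845
0.113383587032
0.094764442253
0.166760405468
0.198443950025
0.250962447063
0.252291914707
0.282190000571
0.303257956406
0.337212905073
0.334761722733
0.391702532474
0.41473351669
0.392492536074
0.469388660452
0.518659875829
0.493142427468
0.5495451901
0.608839746102
0.631309716388
0.635727534997
0.675435886312
0.683850410626
0.730380236944
0.729051631356
0.770525330082
0.794065171643
0.809546875159
0.832513876407
0.855841799858
0.868979740195
0.891701852761
0.90013424266
0.920297782837
0.929642108368
0.943197150588
0.955752534654
0.961333510276
0.970717728979
0.977532211596
0.983733799572
0.989293835146
0.993346073804
0.9963793197
0.998474483385
0.999601614759
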