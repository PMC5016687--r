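# probe_total_M=1e-08
# replicate=r1
# effector=apo
titrant_monomer_M,delta_r
0,-0.00286690801149865
1.05263157894737e-07,0.0153012447505601
2.10526315789474e-07,0.0264471490172743
3.1578947368421e-07,0.0398369014438344
4.21052631578947e-07,0.0503033891270151
5.26315789473684e-07,0.0532656734618435
6.31578947368421e-07,0.0608010376464668
7.36842105263158e-07,0.0622487171351776
8.42105263157895e-07,0.0677290488661522
9.47368421052631e-07,0.0751992405380249
1.05263157894737e-06,0.0716762524179048
1.15789473684211e-06,0.0891300499984222
1.26315789473684e-06,0.0765869557461093
1.36842105263158e-06,0.085176614330557
1.47368421052632e-06,0.0864250879567087
1.57894736842105e-06,0.0862824488180531
1.68421052631579e-06,0.0829842689699133
1.78947368421053e-06,0.0860756187497247
1.89473684210526e-06,0.0921444001953717
2e-06,0.0856633103173746
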