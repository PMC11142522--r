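0.000000 0.088961 -0.289496 0.361771 -0.312245 -0.159565 0.288551 -0.595946 0.430037 -0.031260 -0.566759 0.705023 -0.584299 0.049021 0.581581 -0.887931 0.853063 -0.153420 -0.138718 0.795549 -0.788950 0.539234 0.459039 -0.751698 0.928501 -0.599550 0.005105 0.621000 -0.972144 0.815672 0.027474 -0.597000 0.994170 -0.943953 0.300191 0.303158 -0.960796 0.922251 -0.327998 -0.335268 0.832284 -0.780834 0.519215 -0.170468 -0.768843 0.837796 -0.652250 -0.161598 0.441019 -0.903417 0.741576 -0.360318 -0.284815 0.722713 -0.656583 0.346632 0.265511 -0.566260 0.546966 -0.140305 0.011191 0.454699 -0.410369 0.239579 -0.037944
0.000000 -0.137522 0.099764 0.207738 -0.480353 0.416998 -0.394450 0.044288 0.481934 -0.707019 0.561942 -0.023926 -0.515009 0.714696 -0.562794 0.285775 0.297431 -0.887808 0.875693 -0.292498 -0.281896 0.780418 -0.785462 0.567168 -0.282734 -0.800144 0.989810 -0.770900 -0.017628 0.574869 -0.985617 0.786428 0.020443 -0.312641 0.940618 -0.938238 0.269567 0.307941 -0.933994 0.931314 -0.554070 -0.576499 0.785586 -0.893649 0.555613 -0.002324 -0.541316 0.871761 -0.785649 -0.004436 0.565821 -0.724668 0.657323 -0.290387 -0.257930 0.718916 -0.656016 0.310711 0.240708 -0.468153 0.446344 -0.348547 0.075038 0.190690 -0.159332
0.000000 0.986496 0.951966 0.908827 0.819612 0.894792 0.872438 0.801803 0.763418 0.706503 0.602500 0.708781 0.627185 0.697716 0.587390 0.360432 0.428740 0.433888 0.462514 0.530610 0.545979 0.316503 0.415130 0.336558 0.240722 0.017606 0.142300 0.141675 0.233719 -0.064850 0.166748 0.158500 0.105866 -0.105866 -0.158500 -0.166748 0.064850 -0.233719 -0.141675 -0.142300 -0.017606 -0.240722 -0.336558 -0.415130 -0.316503 -0.545979 -0.530610 -0.462514 -0.433888 -0.428740 -0.360432 -0.587390 -0.697716 -0.627185 -0.708781 -0.602500 -0.706503 -0.763418 -0.801803 -0.872438 -0.894792 -0.819612 -0.908827 -0.951966 -0.986496
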