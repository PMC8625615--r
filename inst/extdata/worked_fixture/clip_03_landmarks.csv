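"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,24.05,21.16,23.34,27.68,33.4,40.64,43.56,53.04,56.18,62.28,70.67,77.19,82.09,88.74,89.36,94.53,93.52,25.59,33.16,37.16,41.49,49.54,68.46,72.43,78.79,82.4,85.7,57.74,57.58,56.38,56.49,48.47,53.97,56.88,62.07,65.76,46.79,43.4,34.55,28.84,34.84,42.47,83.87,79.41,72.76,70.95,73,80.5,74.66,71.46,63.45,56.72,49.93,43.16,41.36,43.92,50.37,58.66,66.07,71.92,66.47,64.96,57.56,48.78,49.01,50.32,57.31,63.65,51.21,61.24,68.2,74.4,83.18,87.93,91.36,94.56,95.25,91.74,91.16,86.52,82.29,77.44,67.95,58.35,52.96,31.41,30.97,30.47,31.84,31.51,33.22,30.59,29.16,30.33,32.27,40.98,45.24,50.65,57.96,60.5,61.13,62.38,58.93,58.73,41.03,37.32,36.82,39.73,42.88,41.67,39.62,38.92,37.94,40.83,41.62,41.25,72.23,69.62,68.79,66.6,66.53,69.2,73.11,77.88,79.4,81.34,80.87,76.81,73.41,72.2,69.93,70.36,73.87,75.97,75.57,75.07
2,23.49,23.36,24.44,27.94,37.11,37.64,46.34,50.54,57.11,66.85,71.31,77.88,79.79,89.41,89.92,95.68,94.08,28.38,32.09,38.54,45.68,50.96,69.58,73.89,78.6,81.49,86.5,57.23,58.87,56.75,57.86,51.09,54.58,57.5,61.18,65.89,46.63,41.37,36.78,32.53,34.42,43.46,84.84,82.67,74.82,70.9,74.18,81.79,75.14,75.78,65.18,59.19,51.21,44.65,42,43.9,52.64,59.89,65.07,71.68,70.15,66.09,59.79,50.15,49.84,52.74,57.64,65.25,52.98,59.48,65.8,73.07,80.93,86.74,90.6,91.26,93.66,94.08,90.27,85.67,79.81,73.9,65.19,60.2,50,31,29.55,29.97,30.9,31.96,30.37,29.98,27.15,29.69,30.17,40.64,43.81,49.73,56.96,58.58,62.03,61.59,58.89,58.99,38.33,36.11,36.91,39.32,40.16,41.5,37.84,37.51,33.96,38.21,42.34,41.31,74.41,70.12,67.19,66.39,68.78,71,74.14,78.7,81.33,82.71,81.58,78.88,75.32,72.4,69.55,72.44,74.43,76.37,78.99,77.19
3,22.68,22.48,25.73,25.24,31.62,37.67,42.89,51.61,56.58,62,69.47,77.63,81.83,85.67,90.57,91.98,92.76,27.13,31.96,37.97,42.8,48.4,66.53,71.78,76.38,81.96,87.64,57.91,55.93,56.46,56.28,48.46,53.26,57.91,60.66,64.25,43.76,39.89,34.6,31.08,32.16,41.25,81.18,80.19,71.94,68.98,73.1,81.14,73.46,71.37,64.5,57.1,48.75,44.95,40.79,44.38,50.97,58.42,64.2,69.99,67.91,63.92,58.2,48.98,48.29,51.05,56.99,61.81,47.1,58.18,66.05,74.62,81.29,85.46,90.39,93,93.21,91.71,88.13,87.2,82.61,74.28,64.82,57.9,49.49,30.34,29.43,29.28,30.06,30.05,29.76,29.4,27.47,29.21,30,41.25,43.48,49.85,50.9,57.91,58.52,61.42,58.04,58.79,39.34,36.89,35.75,37.03,42.73,40.85,36.86,34.92,37.62,37.77,40.74,41.82,75.2,71.14,66.17,69.23,68.87,69.22,73.75,77.83,79.69,82.07,80.51,77.94,74.47,71.17,69.98,71.48,75.36,74.55,77.23,77.54
4,21.23,20.4,24.13,26.75,31.18,34.82,41.55,48.68,56.51,60.86,69.33,75.92,79.88,82.96,87.36,90.5,91.58,26.73,31.25,36.69,40.89,46.82,65.83,69.74,76.34,81.59,84.75,56.03,56.45,56,54.42,48.58,52.66,54.28,58.6,65.12,45.46,39.29,33.46,28.64,33.28,39.98,80.26,79.35,72.9,69.03,72.1,78.71,71.03,70.14,63.22,55.55,45.31,40.97,41.35,43.61,49.81,56.27,64.68,67.79,65.03,63.83,54.56,48.03,45.96,48.66,56.22,62.96,50.42,59.45,67.36,74.02,81.1,86.72,91.03,92.91,94.04,91.42,89.9,86.76,81.1,75.49,66.59,57.06,51,32.12,31.65,29.49,29.59,31.25,32.42,31.64,27.46,29.31,32.53,38.75,45.24,50.84,54.5,59.57,61.26,61.47,59.84,58.2,39.71,37.5,37.04,37.72,41.11,40.19,39.33,37.2,37.83,40.16,42.25,41.97,73.1,69.26,65.37,64.38,64.67,68.14,73.18,77.1,79.56,79.41,78.67,76.34,73.48,69.17,67.26,71.8,72.46,75.09,77.62,76.19
5,17.44,20,19.16,23.11,28.14,34.41,39.39,46.02,51.4,58.84,65.05,72.62,77.41,82.16,85.68,88.06,88.26,24.44,27.09,32.95,37.41,44.7,64.08,66.51,72.45,77.69,80.69,52.92,54.45,50.4,51.66,43.39,48.26,53.76,55.07,63.2,41.43,37.68,31.28,26.91,29.86,34.98,79.83,77.21,68.62,66.03,68.82,76.58,68.98,66.12,62.29,52.3,43.81,39.83,37.57,38.75,46.99,53.98,60.38,65.17,62.92,61.43,53.1,43.63,44.4,45.51,51.51,61.1,50.91,57.42,68.75,77.08,82.61,86.31,90.88,90.98,94.28,92.29,90.99,87.43,81.3,74.9,67.73,57.81,51.79,30.35,31.65,29.93,30.41,31.83,31.44,30.05,28.24,28.64,32,41.22,43.23,49.54,56.6,58.89,60.55,60.34,59.84,59.09,40.72,38.7,36.9,40.48,41.83,40.67,38.6,37.67,35.73,38.73,42.81,41.05,70.28,70.09,66.43,65.15,66.3,67.57,74,76.69,78.77,79.67,78.63,76.4,74.15,70.39,69.29,70.1,71.52,74.33,77.57,73.76
6,19.63,18.47,18.2,21.98,27.84,33.28,37.56,43.26,52.23,59.2,64.93,70.81,75.52,81.23,85.29,87.98,87.99,24.64,27.5,31.29,37,40.96,62.5,64.01,69.86,76.59,80.8,51.77,54.35,51.22,51.62,44.52,46.88,52.82,55.56,60.1,40.15,36.63,26.88,26.89,29.98,35.96,78.75,75.73,67.72,64.94,67.33,74.73,66.66,66.42,58.89,54.04,43.59,38.37,35.9,37.69,44.32,52.2,59.4,65.67,61.87,58.52,51.09,43.84,44.47,42.47,51.14,58.42,50.46,58.24,67.48,72.5,81.98,85.35,89.4,92.22,92.95,89.96,89.06,85.83,81.14,74.86,64.88,55.98,52.3,31.98,29.45,29.06,29.94,28.58,32.12,28.78,26.46,28.67,29.67,39.2,42.7,49.54,56.88,57.41,59.85,60.56,57.99,56.66,38.65,35.13,35.85,35.05,40.42,40.24,37.08,38.88,37.4,37.47,40,42.44,71.75,70.58,67.87,65.57,68.37,69.14,72.14,78.91,80.73,81.3,79.33,75.49,72.84,71.15,70.46,71.8,76.21,76.84,78.19,76.76
7,20.98,20.54,23.18,25.4,28.33,36.04,41.81,46.52,55.58,61.47,68.51,75.51,78.49,83.54,86.51,89.91,92.01,26.01,31.36,36.71,40.69,45.57,65.94,70.91,73.36,80.37,82.6,55.57,55.44,55.5,53.09,46.65,52.19,53.43,60.26,64.99,44.99,39.58,31.92,29.8,30.99,39.85,81.39,78.36,72.13,68.38,71.87,78.24,71.74,69.17,63.34,54.78,47.59,40.52,39.61,40.09,49.17,56.27,61.37,68.57,64.06,63.98,54.43,45.44,44.61,46.84,55.2,60.82,50.68,60.98,68.88,75.45,83.18,87.77,92.08,93.36,94.85,92.57,91.63,88.08,83.74,75.96,68.19,59.41,52.08,31.83,30.15,28.92,31.28,32.12,32.21,31.46,28.02,30.3,32.07,41.31,43.99,49.59,56.74,59.45,60.38,61.68,60.64,58.13,39.87,37.84,37.35,38.2,43.35,42.05,40.2,36.39,37.09,38.2,44.33,42.87,75.74,70.4,68.97,67.28,68.4,72.61,73.92,78.54,81.97,82.11,83.31,80.16,76.05,74.24,71.03,74.1,76.33,78.1,77.96,79.09
8,22.77,21.53,22.71,25.79,30.18,33.81,42.2,49.36,55.46,62.68,70.65,76,78.58,84.42,89.09,91.09,91.51,27.46,31.21,36.16,40.9,48,66.1,70.01,74.75,80.01,84.85,54.71,55.27,56.09,56.75,47.07,51.38,56.97,58.74,62.72,44.83,38.06,33.53,29.41,33.72,38.68,82.9,79.65,73.53,68.83,73.39,79.76,72.5,69.47,62.39,56.63,46.55,42.84,39.17,42.68,49.18,56.83,61.83,69.9,67.55,62.47,54.71,49.65,47.77,50.77,54.19,61.06,47.55,57.04,64.22,73.33,81.11,85.22,88.19,91.55,90.92,89.61,90.19,83.62,78.47,71.17,63.32,57.13,49.8,29.15,28.13,28.06,27.25,28.3,30.13,26.95,26.33,24.48,29.91,37.35,41.68,47.99,51.78,57.2,57.53,57.75,58.51,55.38,38.8,34.16,34.49,34.71,37.49,40.35,35.3,33.67,35.45,37,40.09,39.03,69.61,67.03,62.1,62.25,64.87,64.88,70.28,73.65,78.25,77.63,80.43,72.9,71.44,67.4,66.95,67.43,68.2,72.35,75.07,71.56
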